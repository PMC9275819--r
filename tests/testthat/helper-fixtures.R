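# shared fixtures, all generated in code

tiny_layout <- function(rows = 4, cols = 4, n_blocks = 2) {
  ng <- (rows / 2) * (cols / n_blocks)
  sim_config(rows = rows, cols = cols, n_blocks = n_blocks,
             n_genotypes = ng, seed = 1)
}

# a small complete field study; memoised per options so repeated tests reuse
small_study <- local({
  cache <- list()
  function(seed = 1, ...) {
    key <- paste(seed, rlang::hash(list(...)))
    if (is.null(cache[[key]])) {
      cache[[key]] <<- simulate_field_study(
        sim_config(rows = 8, cols = 8, n_blocks = 4, n_genotypes = 8,
                   seed = seed, ...))
    }
    cache[[key]]
  }
})

# construct an empirical_variogram object directly from known values
make_ev <- function(lag, gamma, n_pairs, cutoff = max(lag)) {
  structure(tibble::tibble(lag = lag, gamma = gamma,
                           n_pairs = as.integer(n_pairs)),
            class = c("empirical_variogram", class(tibble::tibble())),
            cutoff = cutoff, n_lags = length(lag))
}

# wide OTU tibble from a plain count matrix
make_otus <- function(counts, plot_ids = NULL, compartment = "soil") {
  n <- nrow(counts)
  plot_ids <- plot_ids %||% sprintf("plot_%03d", seq_len(n))
  colnames(counts) <- colnames(counts) %||%
    sprintf("otu_%02d", seq_len(ncol(counts)))
  dplyr::bind_cols(
    tibble::tibble(sample_id = paste0(plot_ids, "_", compartment),
                   plot_id = plot_ids, compartment = compartment),
    tibble::as_tibble(counts)
  )
}

`%||%` <- rlang::`%||%`

# smooth spatial pseudo-covariates on a layout, for adjustment tests
fake_pcs <- function(layout, k = 2, seed = 1) {
  out <- tibble::tibble(plot_id = layout$plot_id)
  m <- variogram_model("exponential", 0.1, 1, 3)
  for (j in seq_len(k)) {
    out[[paste0("PC", j, "_krig")]] <-
      simulate_grf(cbind(layout$row, layout$col), m, seed = seed * 10 + j)
  }
  out
}
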