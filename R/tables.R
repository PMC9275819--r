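#' Validate a field layout table
#'
#' A layout describes every plot of a split-plot field trial: its position on
#' the integer plot grid and its design factors. Rows and columns are plain
#' grid indices (distances downstream are Euclidean in plot units).
#'
#' @param layout A data frame with columns `plot_id`, `row`, `col`, `block`,
#'   `treatment`, `genotype`.
#' @return The layout as a tibble with `block`, `treatment` and `genotype`
#'   coerced to factors, invisibly validated:
#'   duplicate `(row, col)` pairs, missing columns, or missing design values
#'   raise an error.
#' @examples
#' layout <- tibble::tibble(
#'   plot_id = paste0("p", 1:4), row = c(0, 0, 1, 1), col = c(0, 1, 0, 1),
#'   block = 1, treatment = c("WW", "WW", "WS", "WS"),
#'   genotype = c("g1", "g2", "g1", "g2")
#' )
#' validate_layout(layout)
#' @export
validate_layout <- function(layout) {
  required <- c("plot_id", "row", "col", "block", "treatment", "genotype")
  missing_cols <- setdiff(required, names(layout))
  if (length(missing_cols) > 0) {
    abort(
      paste0("layout is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "fieldkrige_schema_error"
    )
  }
  layout <- as_tibble(layout)
  if (anyDuplicated(layout$plot_id) > 0) {
    abort("layout has duplicated plot_id values",
          class = "fieldkrige_layout_error")
  }
  rc <- paste(layout$row, layout$col, sep = "\r")
  if (anyDuplicated(rc) > 0) {
    dups <- unique(layout$plot_id[duplicated(rc) | duplicated(rc, fromLast = TRUE)])
    abort(
      paste0("layout has duplicated (row, col) positions for plots: ",
             paste(head(dups, 5), collapse = ", ")),
      class = "fieldkrige_layout_error"
    )
  }
  design <- layout[c("block", "treatment", "genotype")]
  if (anyNA(design) || anyNA(layout$row) || anyNA(layout$col)) {
    abort("layout has missing values in row/col/block/treatment/genotype",
          class = "fieldkrige_layout_error"
    )
  }
  layout$block <- factor(layout$block)
  layout$treatment <- factor(layout$treatment)
  layout$genotype <- factor(layout$genotype)
  layout
}

check_plot_ids <- function(tbl, layout, what) {
  unknown <- setdiff(unique(tbl$plot_id), layout$plot_id)
  if (length(unknown) > 0) {
    abort(
      paste0(what, " refers to plot_id(s) absent from the layout: ",
             paste(head(unknown, 5), collapse = ", ")),
      class = "fieldkrige_referential_error"
    )
  }
  invisible(tbl)
}

#' Read the field tables for a trial
#'
#' Reads the plot layout plus any of the three data tables (soil properties,
#' phenotypes, OTU counts) from delimited text and cross-validates them:
#' every `plot_id` appearing in a data table must exist in the layout. The
#' OTU table is expected wide — `sample_id`, `plot_id`, `compartment`, then
#' one numeric column per OTU (the long form written by other tools can be
#' reshaped with [tidyr::pivot_wider()] first).
#'
#' @param layout_path Path to the layout table
#'   (`plot_id,row,col,block,treatment,genotype`).
#' @param soil_path,phenotype_path,otu_path Optional paths to the soil,
#'   phenotype, and OTU tables. Soil and phenotype tables have one row per
#'   plot (`plot_id` plus one column per property / trait; missing values
#'   allowed for unsampled plots).
#' @param delim Field delimiter; `NULL` (default) guesses from the file
#'   extension (`.csv` comma, otherwise tab).
#' @return A list with elements `layout`, `soil`, `phenotypes`, `otus`
#'   (absent tables are `NULL`), each a tibble.
#' @export
read_field_tables <- function(layout_path, soil_path = NULL,
                              phenotype_path = NULL, otu_path = NULL,
                              delim = NULL) {
  read_one <- function(path) {
    if (is.null(path)) return(NULL)
    d <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    readr::read_delim(path, delim = d, show_col_types = FALSE,
                      progress = FALSE)
  }
  layout <- validate_layout(read_one(layout_path))
  soil <- read_one(soil_path)
  phen <- read_one(phenotype_path)
  otus <- read_one(otu_path)
  for (nm in c("soil", "phen")) {
    tbl <- get(nm)
    if (!is.null(tbl)) {
      if (!"plot_id" %in% names(tbl)) {
        abort(paste0(nm, " table is missing column plot_id"),
              class = "fieldkrige_schema_error")
      }
      check_plot_ids(tbl, layout, nm)
    }
  }
  if (!is.null(otus)) {
    need <- c("sample_id", "plot_id", "compartment")
    miss <- setdiff(need, names(otus))
    if (length(miss) > 0) {
      abort(paste0("OTU table is missing column(s): ",
                   paste(miss, collapse = ", ")),
            class = "fieldkrige_schema_error")
    }
    check_plot_ids(otus, layout, "OTU table")
    validate_otu_table(otus)
  }
  list(layout = layout, soil = soil, phenotypes = phen, otus = otus)
}

#' @rdname read_field_tables
#' @param otus A wide OTU tibble (`sample_id`, `plot_id`, `compartment` and
#'   numeric count columns).
#' @export
validate_otu_table <- function(otus) {
  counts <- otu_counts(otus)
  if (ncol(counts) == 0) {
    abort("OTU table has no count columns", class = "fieldkrige_schema_error")
  }
  if (any(counts < 0, na.rm = TRUE)) {
    abort("OTU table contains negative counts",
          class = "fieldkrige_domain_error")
  }
  if (anyDuplicated(otus$sample_id) > 0) {
    abort("OTU table has duplicated sample_id values",
          class = "fieldkrige_schema_error")
  }
  as_tibble(otus)
}

otu_meta_cols <- c("sample_id", "plot_id", "compartment")

#' Extract the numeric count matrix from a wide OTU table
#'
#' @param otus A wide OTU tibble.
#' @return A numeric matrix (samples x OTUs) with `sample_id` rownames.
#' @export
otu_counts <- function(otus) {
  keep <- setdiff(names(otus), otu_meta_cols)
  m <- as.matrix(otus[keep])
  storage.mode(m) <- "double"
  rownames(m) <- otus$sample_id
  m
}

#' Quality-control filter for an OTU count table
#'
#' Applies the two depth filters used for amplicon count tables, in a fixed
#' order: first samples whose total read count across all OTUs is below
#' `min_sample_depth` are removed, then — on the retained samples — OTUs
#' whose grand total is below `min_otu_total` or above `max_otu_total` are
#' removed. All comparisons are strict, so a sample at exactly
#' `min_sample_depth` is kept. The operation is idempotent only in the
#' fixed-point sense: it is re-applied internally until no further rows or
#' columns drop, so filtering twice equals filtering once.
#'
#' @param otus A wide OTU tibble (see [read_field_tables()]).
#' @param min_sample_depth Minimum per-sample total (default 10000).
#' @param min_otu_total,max_otu_total Bounds on the per-OTU grand total
#'   (defaults 100 and 200000).
#' @return The filtered tibble, with attributes `n_samples_dropped` and
#'   `n_otus_dropped`.
#' @export
filter_otu_table <- function(otus, min_sample_depth = 10000,
                             min_otu_total = 100, max_otu_total = 200000) {
  otus <- as_tibble(otus)
  n0_samples <- nrow(otus)
  n0_otus <- length(setdiff(names(otus), otu_meta_cols))
  repeat {
    counts <- otu_counts(otus)
    keep_samples <- rowSums(counts) >= min_sample_depth
    otus <- otus[keep_samples, , drop = FALSE]
    if (nrow(otus) == 0) {
      abort("all samples removed by the depth filter",
            class = "fieldkrige_empty_table_error")
    }
    counts <- otu_counts(otus)
    totals <- colSums(counts)
    keep_otus <- totals >= min_otu_total & totals <= max_otu_total
    otus <- otus[c(otu_meta_cols, colnames(counts)[keep_otus])]
    if (all(keep_samples) && all(keep_otus)) break
  }
  attr(otus, "n_samples_dropped") <- n0_samples - nrow(otus)
  attr(otus, "n_otus_dropped") <-
    n0_otus - length(setdiff(names(otus), otu_meta_cols))
  otus
}

#' Scale all samples of an OTU table to a common sequencing depth
#'
#' Every sample's counts are multiplied by a single factor so that all sample
#' totals equal the maximum observed total. Per-sample proportions and zeros
#' are unchanged; scaled counts are kept as real numbers (count models
#' downstream round their own copies).
#'
#' @param otus A filtered wide OTU tibble with positive sample totals.
#' @return The depth-scaled tibble.
#' @export
scale_to_common_depth <- function(otus) {
  counts <- otu_counts(otus)
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    abort(paste0("sample(s) with zero total reads cannot be depth-scaled: ",
                 paste(head(otus$sample_id[totals <= 0], 5), collapse = ", ")),
          class = "fieldkrige_domain_error")
  }
  target <- max(totals)
  scaled <- counts * (target / totals)
  out <- otus
  out[colnames(counts)] <- as_tibble(scaled)
  out
}

#' Write the field tables produced by the pipeline
#'
#' Tab-separated output with a stable column order (metadata columns first,
#' data columns in their current order).
#'
#' @param tbl A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
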