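# GWAS-ready phenotype statistics across accessions: per-trait
# summaries (mean, sd, CV%), one-pass Z-score outlier removal at a
# configurable |Z| threshold, pairwise-complete Pearson correlations,
# and export in the Taxa-keyed layout association tools expect.

#' Statistics configuration
#'
#' @param z_threshold Positive |Z| at or above which a trait value is
#'   treated as an outlier and removed (cell set to missing).
#' @param ddof Delta degrees of freedom for standard deviations
#'   (0 = population, matching the trait extractor).
#' @return A list of class `stats_config`.
#' @export
stats_config <- function(z_threshold = 4, ddof = 0) {
  stopifnot(z_threshold > 0, ddof >= 0)
  structure(list(z_threshold = z_threshold, ddof = ddof),
            class = "stats_config")
}

#' Coerce a data frame into an accession-by-trait matrix
#'
#' @param df Data frame whose first identifier column is `image_id`,
#'   `accession_id` or `Taxa`, followed by the 24 trait columns.
#' @return A list of class `trait_matrix`: `accession_ids` (character)
#'   and `values` (numeric matrix, accessions x 24 traits).
#' @export
as_trait_matrix <- function(df) {
  if (inherits(df, "trait_matrix")) return(df)
  id_col <- intersect(c("accession_id", "image_id", "Taxa"), names(df))[1L]
  if (is.na(id_col)) stop("trait matrix needs an accession_id/image_id/Taxa column")
  if (!all(trait_names() %in% names(df))) {
    stop("trait matrix needs all 24 trait columns (see trait_names())")
  }
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) stop("duplicate accession ids in trait matrix")
  values <- as.matrix(df[, trait_names()])
  mode(values) <- "numeric"
  rownames(values) <- ids
  structure(list(accession_ids = ids, values = values), class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("<trait_matrix> %d accession(s) x %d traits (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Per-trait summary statistics
#'
#' @param m A trait matrix ([as_trait_matrix()]).
#' @param config A [stats_config()] (only `ddof` is used).
#' @return Data frame with one row per trait: `trait`, `n_nonmissing`,
#'   `mean`, `sd`, `cv_percent` (100*sd/mean, missing when the mean is
#'   0). An all-missing trait yields a row of missing values.
#' @export
summarize_traits <- function(m, config = stats_config()) {
  m <- as_trait_matrix(m)
  rows <- lapply(colnames(m$values), function(tr) {
    x <- m$values[, tr]
    x <- x[!is.na(x)]
    if (length(x) == 0L) {
      return(data.frame(trait = tr, n_nonmissing = 0L, mean = NA_real_,
                        sd = NA_real_, cv_percent = NA_real_))
    }
    mu <- mean(x)
    s <- sd_ddof(x, config$ddof)
    data.frame(trait = tr, n_nonmissing = length(x), mean = mu, sd = s,
               cv_percent = if (mu != 0) 100 * s / mu else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-pass Z-score outlier removal
#'
#' For each trait independently, Z-scores are computed from the mean and
#' standard deviation of the unfiltered non-missing values; cells with
#' `|Z| >= z_threshold` are set to missing. A single pass only — the
#' mean/sd are never recomputed from the filtered data. Traits with zero
#' standard deviation are left untouched.
#'
#' @param m A trait matrix.
#' @param config A [stats_config()].
#' @return A list with `filtered` (the trait matrix with outlier cells
#'   missing) and `removals` (data frame `accession_id`, `trait`,
#'   `value`, `z` listing every removed cell).
#' @export
zscore_filter <- function(m, config = stats_config()) {
  m <- as_trait_matrix(m)
  values <- m$values
  logs <- list()
  for (tr in colnames(values)) {
    x <- values[, tr]
    ok <- !is.na(x)
    if (sum(ok) == 0L) next
    mu <- mean(x[ok])
    s <- sd_ddof(x[ok], config$ddof)
    if (s == 0) next
    z <- (x - mu) / s
    hit <- ok & abs(z) >= config$z_threshold
    if (any(hit)) {
      logs[[tr]] <- data.frame(accession_id = m$accession_ids[hit], trait = tr,
                               value = x[hit], z = z[hit])
      values[hit, tr] <- NA_real_
    }
  }
  removals <- if (length(logs) > 0L) do.call(rbind, logs) else
    data.frame(accession_id = character(0), trait = character(0),
               value = numeric(0), z = numeric(0))
  rownames(removals) <- NULL
  list(filtered = structure(list(accession_ids = m$accession_ids,
                                 values = values), class = "trait_matrix"),
       removals = removals)
}

#' Pairwise-complete Pearson correlation matrix of the 24 traits
#'
#' @param m A trait matrix.
#' @param min_obs Minimum number of pairwise-complete observations for a
#'   cell to be reported; cells below it are missing, as are pairs
#'   involving a zero-variance trait.
#' @return A symmetric 24 x 24 matrix with unit diagonal, entries in
#'   \[-1, 1\] or missing.
#' @export
pearson_matrix <- function(m, min_obs = 3L) {
  m <- as_trait_matrix(m)
  v <- m$values
  r <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs",
                                   method = "pearson"))
  obs <- crossprod(!is.na(v)) # pairwise-complete counts
  r[obs < min_obs] <- NA_real_
  diag(r) <- ifelse(colSums(!is.na(v)) > 0L, 1, NA_real_)
  r
}

#' Export a GWAS phenotype table
#'
#' First column `Taxa` (accession id), then the 24 trait columns in
#' fixed order; missing values written as `"NA"` — the layout consumed
#' by rMVP/GAPIT-style association pipelines.
#'
#' @param m A trait matrix.
#' @param path Output CSV path, or `NULL` to return the data frame.
#' @return The data frame written, invisibly when `path` given.
#' @export
export_phenotypes <- function(m, path = NULL) {
  m <- as_trait_matrix(m)
  out <- data.frame(Taxa = m$accession_ids, as.data.frame(m$values))
  rownames(out) <- NULL
  if (is.null(path)) return(out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(out)
}
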