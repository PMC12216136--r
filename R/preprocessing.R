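#' Fit per-feature standardization statistics
#'
#' Computes the column means and standard deviations used by the Z-score
#' transform `x_new = (x - mu) / sigma`, after which every feature has mean
#' 0 and standard deviation 1 on the fitting data.
#'
#' @param X Numeric matrix (rows = samples). At least 2 rows, no missing
#'   values (missingness is handled upstream of this pipeline).
#' @param sd_type `"sample"` (divisor n-1, default) or `"population"`
#'   (divisor n).
#' @return An object of class `norm_stats`: list with `mu`, `sigma`,
#'   `feature_names`, `sd_type`.
#' @export
fit_normalizer <- function(X, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to fit a normalizer")
  if (anyNA(X)) stop("missing values are not supported; impute upstream")
  nm <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  if (sd_type == "population") sigma <- sigma * sqrt((nrow(X) - 1) / nrow(X))
  bad <- which(!(sigma > 0))
  if (length(bad))
    stop("degenerate (zero-variance) column(s): ", paste(nm[bad], collapse = ", "))
  structure(list(mu = setNames(as.numeric(mu), nm),
                 sigma = setNames(as.numeric(sigma), nm),
                 feature_names = nm, sd_type = sd_type),
            class = "norm_stats")
}

#' Apply (or invert) the Z-score transform
#'
#' @param X Numeric matrix with the same number of columns as the fitted
#'   statistics.
#' @param stats A `norm_stats` object from [fit_normalizer()].
#' @return Matrix of the same shape, standardized column-wise.
#' @export
apply_zscore <- function(X, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  X <- as.matrix(X)
  if (ncol(X) != length(stats$mu))
    stop("dimension mismatch: ", ncol(X), " columns vs ", length(stats$mu), " fitted")
  out <- sweep(sweep(X, 2, stats$mu, "-"), 2, stats$sigma, "/")
  colnames(out) <- stats$feature_names
  out
}

#' @rdname apply_zscore
#' @export
invert_zscore <- function(X, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  sweep(sweep(as.matrix(X), 2, stats$sigma, "*"), 2, stats$mu, "+")
}

#' Serialize normalization statistics to / from JSON
#'
#' Small provenance document mapping each feature name to its `mu` and
#' `sigma`, so a fitted normalizer can travel with pipeline outputs.
#'
#' @param stats A `norm_stats` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
normalizer_to_json <- function(stats, path = NULL) {
  stopifnot(inherits(stats, "norm_stats"))
  doc <- list(sd_type = stats$sd_type,
              features = lapply(seq_along(stats$mu), function(j)
                list(name = stats$feature_names[j],
                     mu = stats$mu[[j]], sigma = stats$sigma[[j]])))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname normalizer_to_json
#' @param json JSON string or file path produced by [normalizer_to_json()].
#' @export
normalizer_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  nm <- vapply(doc$features, `[[`, "", "name")
  structure(list(mu = setNames(vapply(doc$features, `[[`, 0, "mu"), nm),
                 sigma = setNames(vapply(doc$features, `[[`, 0, "sigma"), nm),
                 feature_names = nm, sd_type = doc$sd_type),
            class = "norm_stats")
}
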