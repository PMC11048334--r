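# Chronology statistics: Pearson correlations between annual series, mean
# inter-series correlation per ring parameter, site chronologies, and
# significance via the two-tailed t-test (df = n - 2). Missing years are
# handled by pairwise-complete overlap; nothing is imputed.

align_series <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  } else if (length(x) != length(y)) {
    stop("unnamed series must have equal length; name values by year to align on overlap")
  }
  keep <- is.finite(x) & is.finite(y)
  list(x = as.numeric(x[keep]), y = as.numeric(y[keep]))
}

#' Pearson correlation with two-tailed t-test
#'
#' Product-moment correlation on the pairwise-complete overlap of two annual
#' series (aligned by year names when present), with significance from the
#' two-tailed t-test: \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on `n - 2` degrees of
#' freedom. Requires an overlap of at least `min_overlap` years and non-zero
#' variance in both series.
#'
#' @param x,y Numeric series; if named, names are treated as years and the
#'   correlation uses the common years only.
#' @param min_overlap Minimum number of common years (default 3).
#' @return Object of class `pic_cor`: list with `r`, `n` (overlap) and `p`
#'   (two-tailed).
#' @export
pearson_test <- function(x, y, min_overlap = 3L) {
  al <- align_series(x, y)
  n <- length(al$x)
  if (n < min_overlap)
    stop(sprintf("insufficient overlap: %d common observations (need >= %d)", n, min_overlap))
  if (stats::sd(al$x) == 0 || stats::sd(al$y) == 0)
    stop("undefined correlation: zero variance in one of the series")
  r <- cor(al$x, al$y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), df = n - 2)
  }
  structure(list(r = r, n = n, p = p), class = "pic_cor")
}

#' @export
print.pic_cor <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, two-tailed p = %.4g)\n", x$r, x$n, x$p))
  invisible(x)
}

#' Mean inter-series correlation for one ring parameter
#'
#' Measures the common external signal shared by specimens: the arithmetic
#' mean of Pearson correlations over all specimen pairs (default), or of each
#' specimen's correlation with the mean chronology of the remaining specimens
#' (`method = "mean_chronology"`, the leave-one-out rbar convention of
#' dendrochronology). Pairs with fewer than `min_overlap` common years or
#' zero variance are dropped and reported.
#'
#' @param series Named list of year-named numeric vectors, one per specimen
#'   (see [series_from_records()]).
#' @param method `"pairwise"` or `"mean_chronology"`.
#' @param min_overlap Minimum common years per correlation.
#' @return List with `mean_r`, `n_used`, `correlations` (data frame) and
#'   `dropped` (character vector of skipped pairs).
#' @export
interseries_correlation <- function(series,
                                    method = c("pairwise", "mean_chronology"),
                                    min_overlap = 3L) {
  method <- match.arg(method)
  if (length(series) < 2L) stop("need series from at least two specimens")
  ids <- names(series)
  if (is.null(ids)) ids <- as.character(seq_along(series))
  rows <- list(); dropped <- character()
  if (method == "pairwise") {
    for (i in seq_along(series)[-length(series)]) for (j in (i + 1L):length(series)) {
      res <- tryCatch(pearson_test(series[[i]], series[[j]], min_overlap),
                      error = function(e) e)
      if (inherits(res, "error")) {
        dropped <- c(dropped, sprintf("%s~%s: %s", ids[i], ids[j], conditionMessage(res)))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(a = ids[i], b = ids[j],
                                                r = res$r, n = res$n, p = res$p)
      }
    }
  } else {
    for (i in seq_along(series)) {
      others <- site_chronology(series[-i])
      ref <- others$value; names(ref) <- others$year
      res <- tryCatch(pearson_test(series[[i]], ref, min_overlap),
                      error = function(e) e)
      if (inherits(res, "error")) {
        dropped <- c(dropped, sprintf("%s~mean: %s", ids[i], conditionMessage(res)))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(a = ids[i], b = "mean(others)",
                                                r = res$r, n = res$n, p = res$p)
      }
    }
  }
  if (length(dropped))
    warning("correlations skipped: ", paste(dropped, collapse = "; "))
  if (!length(rows)) stop("no specimen pair had sufficient overlap")
  correlations <- do.call(rbind, rows)
  list(mean_r = mean(correlations$r), n_used = nrow(correlations),
       correlations = correlations, dropped = dropped)
}

#' Site chronology: per-year mean across specimens
#'
#' Averages specimen series year by year over the specimens present in each
#' year (the sample depth), without imputation.
#'
#' @param series Named list of year-named numeric vectors.
#' @return `data.frame` with `year`, `value` and `depth`, sorted by year.
#' @export
site_chronology <- function(series) {
  if (length(series) == 0L) stop("no series supplied")
  years <- sort(unique(unlist(lapply(series, names))))
  if (is.null(years)) stop("series must be named by year")
  vals <- vapply(years, function(y) {
    v <- unlist(lapply(series, function(s) unname(s[y])))
    v <- v[is.finite(v)]
    c(mean(v), length(v))
  }, numeric(2))
  data.frame(year = as.integer(years), value = vals[1, ], depth = as.integer(vals[2, ]))
}

#' Correlation matrix between ring-parameter chronologies
#'
#' Builds the site chronology of each ring parameter (ring width and mean,
#' maximum, minimum porosity) and computes the symmetric matrix of Pearson
#' correlations between them on common years, with two-tailed p-values and a
#' significance mask at `alpha` (no multiple-testing correction; raw p-values
#' are reported).
#'
#' @param records Ring-record `data.frame` from [build_series()], or a named
#'   list of pre-built chronologies (year-named numeric vectors).
#' @param parameters Character vector of parameters to include.
#' @param alpha Significance level for the mask (default 0.05).
#' @return Object of class `param_cor_matrix`: list of matrices `r`, `p`,
#'   `n`, logical `significant`, and `alpha`.
#' @export
parameter_correlation_matrix <- function(records,
                                         parameters = c("RW", "MEAN_Por", "MAX_Por", "MIN_Por"),
                                         alpha = 0.05) {
  chron <- if (is.data.frame(records)) {
    lapply(stats::setNames(parameters, parameters), function(p) {
      sc <- site_chronology(series_from_records(records, p))
      stats::setNames(sc$value, sc$year)
    })
  } else {
    if (is.null(names(records))) stop("chronology list must be named")
    records[parameters]
  }
  k <- length(chron)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(names(chron), names(chron)))
  diag(r) <- 1; diag(p) <- 0
  diag(nmat) <- vapply(chron, length, integer(1))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    res <- pearson_test(chron[[i]], chron[[j]])
    r[i, j] <- r[j, i] <- res$r
    p[i, j] <- p[j, i] <- res$p
    nmat[i, j] <- nmat[j, i] <- res$n
  }
  structure(list(r = r, p = p, n = nmat, significant = p < alpha, alpha = alpha),
            class = "param_cor_matrix")
}

#' @export
print.param_cor_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Parameter correlation matrix (* marks p < %.2g):\n", x$alpha))
  disp <- matrix(sprintf(paste0("%.", digits, "f%s"), x$r,
                         ifelse(x$significant & row(x$r) != col(x$r), "*", " ")),
                 nrow = nrow(x$r), dimnames = dimnames(x$r))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Write a parameter correlation matrix to CSV
#'
#' Long format: one row per parameter pair with `r`, `n` and `p`.
#'
#' @param mat A `param_cor_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_param_cor_csv <- function(mat, path) {
  stopifnot(inherits(mat, "param_cor_matrix"))
  nm <- rownames(mat$r)
  idx <- which(upper.tri(mat$r), arr.ind = TRUE)
  df <- data.frame(param_a = nm[idx[, 1]], param_b = nm[idx[, 2]],
                   r = mat$r[idx], n = mat$n[idx], p = mat$p[idx],
                   significant = mat$significant[idx])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
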