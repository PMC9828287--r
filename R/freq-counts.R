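# Frequency-count data model.
#
# The sufficient statistic for every estimator in this package is the
# vector of species frequency counts f_k: the number of species observed
# exactly k times in a sample of individuals. Keys are kept sparse so very
# large multiplicities cost nothing.

#' Construct frequency counts from per-species abundances
#'
#' Tallies an abundance vector (one positive integer count per *observed*
#' species) into species frequency counts \eqn{f_k}, the number of species
#' seen exactly \eqn{k} times. Species absent from the sample are by
#' definition not listed; a zero or negative count in the input is treated
#' as a data error rather than silently dropped.
#'
#' @param x integer vector of per-species counts, all \eqn{\ge 1}. Names,
#'   if present, are taken as species labels and used in error messages.
#' @return An object of class `freq_counts`: a list with components
#'   \describe{
#'     \item{f}{named numeric vector of counts \eqn{f_k}, names are the
#'       multiplicities \eqn{k} in increasing order;}
#'     \item{n}{total number of individuals \eqn{\sum k f_k};}
#'     \item{S_obs}{observed species richness \eqn{\sum f_k};}
#'     \item{sum_sq}{\eqn{\sum k^2 f_k = \sum X_i^2}.}
#'   }
#' @examples
#' fc <- freq_counts(c(1, 1, 2, 3, 3, 5))
#' fc$S_obs  # 6 species
#' fc$n      # 15 individuals
#' @export
freq_counts <- function(x) {
  if (length(x) == 0) stop("abundance vector is empty")
  if (!is.numeric(x)) stop("abundance counts must be numeric integers")
  bad <- which(!is_whole(x) | x < 1)
  if (length(bad) > 0) {
    lab <- if (!is.null(names(x))) names(x)[bad[1]] else as.character(bad[1])
    stop(sprintf(
      "abundance counts must be positive integers; entry '%s' is %s",
      lab, format(x[bad[1]])
    ))
  }
  x <- as.integer(round(x))
  tab <- table(x)
  freq_counts_from_table(as.integer(names(tab)), as.numeric(tab))
}

#' Construct frequency counts from (k, f_k) pairs
#'
#' @param k integer multiplicities (all \eqn{\ge 1}, no duplicates).
#' @param f counts of species observed exactly `k` times. Non-negative;
#'   explicit zeros are retained. Real (non-integer) values are accepted so
#'   that *expected* frequency counts can be pushed through the estimators
#'   for analytic checks; file readers enforce integrality separately.
#' @return A `freq_counts` object; see [freq_counts()].
#' @export
freq_counts_from_table <- function(k, f) {
  if (length(k) != length(f)) stop("k and f must have the same length")
  if (length(k) == 0) stop("empty frequency table")
  if (!all(is_whole(k)) || any(k < 1)) {
    stop("multiplicities k must be integers >= 1")
  }
  k <- as.integer(round(k))
  if (anyDuplicated(k)) {
    stop(sprintf("duplicate multiplicity k = %d in frequency table",
                 k[duplicated(k)][1]))
  }
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0)) {
    stop("frequency counts f_k must be finite and non-negative")
  }
  ord <- order(k)
  k <- k[ord]; f <- as.numeric(f[ord])
  fv <- stats::setNames(f, as.character(k))
  out <- list(
    f = fv,
    n = sum(k * f),
    S_obs = sum(f),
    sum_sq = sum(as.numeric(k)^2 * f)
  )
  if (out$S_obs <= 0) stop("no species observed (all f_k are zero)")
  class(out) <- "freq_counts"
  out
}

#' Look up f_k (zero when k is absent)
#' @param fc a `freq_counts` object.
#' @param k multiplicity (scalar or vector).
#' @return numeric vector of the same length as `k`.
#' @export
fk <- function(fc, k) {
  stopifnot(inherits(fc, "freq_counts"))
  out <- fc$f[as.character(k)]
  out[is.na(out)] <- 0
  unname(out)
}

#' Observed multiplicities of a frequency-count object
#' @param fc a `freq_counts` object.
#' @return integer vector of the stored multiplicities k.
#' @export
multiplicities <- function(fc) as.integer(names(fc$f))

#' @export
print.freq_counts <- function(x, ...) {
  cat(sprintf("Frequency counts: S_obs = %g species, n = %g individuals\n",
              x$S_obs, x$n))
  show <- x$f[x$f > 0]
  kk <- utils::head(names(show), 10)
  cat("  f_k:", paste(sprintf("f%s=%g", kk, show[kk]), collapse = ", "),
      if (length(show) > 10) "..." else "", "\n")
  invisible(x)
}

#' Read abundance or frequency-count data from a delimited text file
#'
#' Abundance format: one record per observed species, either a bare count
#' or `label,count`. Frequency format: records `k,f_k`. Comment lines
#' starting with `#` are skipped; the delimiter (comma or tab) is sniffed
#' from the first data line unless given; an optional header row is
#' detected by a non-numeric final field.
#'
#' @param path path to a UTF-8 text file.
#' @param format `"abundance"` or `"frequency"`.
#' @param sep field delimiter; `NULL` (default) sniffs comma vs tab.
#' @return A `freq_counts` object.
#' @export
read_counts <- function(path, format = c("abundance", "frequency"),
                        sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop(sprintf("no data records in %s", path))
  if (is.null(sep)) {
    sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  fields <- lapply(fields, trimws)
  # header: last field of the first row is not numeric
  first_last <- utils::tail(fields[[1]], 1)
  if (suppressWarnings(is.na(as.numeric(first_last)))) {
    fields <- fields[-1]
    if (length(fields) == 0) stop(sprintf("no data records in %s", path))
  }
  nf <- lengths(fields)
  if (format == "frequency") {
    if (any(nf != 2)) {
      stop("frequency format requires exactly two columns (k, f_k)")
    }
    k <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1)))
    f <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
    if (any(is.na(k)) || any(is.na(f))) {
      stop("non-numeric cell in frequency file")
    }
    if (any(!is_whole(f)) || any(f < 0)) {
      stop("frequency counts f_k must be non-negative integers")
    }
    freq_counts_from_table(k, f)
  } else {
    if (any(nf > 2)) stop("abundance format takes at most two columns")
    counts <- suppressWarnings(
      as.numeric(vapply(fields, function(fl) fl[length(fl)], ""))
    )
    labels <- vapply(seq_along(fields), function(i) {
      if (nf[i] == 2) fields[[i]][1] else as.character(i)
    }, "")
    if (any(is.na(counts))) {
      stop(sprintf("non-numeric abundance for record '%s'",
                   labels[which(is.na(counts))[1]]))
    }
    freq_counts(stats::setNames(counts, labels))
  }
}
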