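# Ground-truth assemblages for simulation.
#
# An assemblage is a true species count S together with a detection
# probability vector p (summing to 1). Seven classical species-abundance
# models are provided, spanning coefficients of variation from 0
# (homogeneous) to 4 (power decay), plus empirical assemblages built from
# observed frequency counts.

#' Coefficient of variation of a probability vector
#'
#' sd(p)/mean(p) with the population (divide-by-S) standard deviation;
#' 0 for a homogeneous assemblage, larger for more heterogeneous ones.
#'
#' @param p vector of positive probabilities (need not be normalised).
#' @return the coefficient of variation.
#' @examples
#' cv_of_probs(rep(1, 100))       # 0
#' cv_of_probs(c(0.9, 0.1))       # 0.8
#' @export
cv_of_probs <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0)) stop("p must be positive and finite")
  sqrt(mean((p - mean(p))^2)) / mean(p)
}

new_assemblage <- function(model, S, p, seed = NULL, label = NULL) {
  p <- p / sum(p)
  structure(
    list(model = model, S = S, p = p, cv = cv_of_probs(p), seed = seed,
         label = label),
    class = "assemblage"
  )
}

#' @export
print.assemblage <- function(x, ...) {
  cat(sprintf("Assemblage '%s': S = %d species, CV = %.3f%s\n",
              x$model, x$S, x$cv,
              if (!is.null(x$seed)) sprintf(", seed = %d", x$seed) else ""))
  invisible(x)
}

#' Build a model assemblage
#'
#' Detection probabilities are \eqn{p_i = c\,a_i} with \eqn{c} normalising
#' to 1. The available models and the distribution of the \eqn{a_i}:
#' \describe{
#'   \item{homogeneous}{\eqn{p_i = 1/S} (CV 0).}
#'   \item{uniform}{\eqn{a_i \sim U(0, 1)} (CV near 0.53).}
#'   \item{negbin}{\eqn{a_i} negative binomial with mean 98 and variance
#'     4900 (size \eqn{98^2/4802 \approx 2}); zero draws are redrawn since
#'     a present species cannot have zero relative abundance (CV near
#'     0.74).}
#'   \item{broken_stick}{\eqn{a_i \sim Exp(1)} (CV near 1).}
#'   \item{lognormal}{\eqn{a_i \sim LogNormal(0, 1)} (CV near 1.3-1.6).}
#'   \item{zipf_mandelbrot}{\eqn{p_i \propto 1/(i + 10)} (CV 1.88).}
#'   \item{power_decay}{\eqn{p_i \propto 1/i^{0.9}} (CV 4).}
#' }
#' Stochastic models draw one realisation per `(model, S, seed)` and the
#' same triple always reproduces it bit-for-bit; deterministic models
#' (homogeneous, zipf_mandelbrot, power_decay) ignore the seed.
#'
#' @param model model id, one of the names above.
#' @param S number of species (\eqn{\ge 2}).
#' @param seed integer seed fixing the realisation; required for the
#'   stochastic models.
#' @return An `assemblage` object with components `model`, `S`, `p`
#'   (normalised probabilities), `cv` and `seed`.
#' @examples
#' make_assemblage("power_decay", 1000)$cv   # ~4
#' @export
make_assemblage <- function(model = c("homogeneous", "uniform", "negbin",
                                      "broken_stick", "lognormal",
                                      "zipf_mandelbrot", "power_decay"),
                            S, seed = NULL) {
  model <- match.arg(model)
  stopifnot(is_whole(S), S >= 2)
  S <- as.integer(S)
  i <- seq_len(S)
  deterministic <- model %in% c("homogeneous", "zipf_mandelbrot",
                                "power_decay")
  if (!deterministic && is.null(seed)) {
    stop(sprintf("model '%s' is stochastic; a seed is required", model))
  }
  a <- switch(model,
    homogeneous = rep(1 / S, S),
    zipf_mandelbrot = 1 / (i + 10),
    power_decay = 1 / i^0.9,
    uniform = with_seed(seed, stats::runif(S)),
    broken_stick = with_seed(seed, stats::rexp(S, rate = 1)),
    lognormal = with_seed(seed, stats::rlnorm(S, meanlog = 0, sdlog = 1)),
    negbin = with_seed(seed, {
      size <- 98^2 / (4900 - 98)
      draw <- stats::rnbinom(S, size = size, mu = 98)
      while (any(draw == 0)) {
        z <- draw == 0
        draw[z] <- stats::rnbinom(sum(z), size = size, mu = 98)
      }
      draw
    })
  )
  new_assemblage(model, S, a, seed = if (deterministic) NULL else seed)
}

#' Multinomial sample from an assemblage
#'
#' Draws individuals with replacement: \eqn{X \sim Multinomial(n, p)},
#' so the sample size is exactly `n`.
#'
#' @param assemblage an [make_assemblage()] or [empirical_assemblage()]
#'   object.
#' @param n sample size (number of individuals, \eqn{\ge 1}).
#' @param seed optional seed for this draw.
#' @return Integer vector of per-species counts (length `S`, zeros for
#'   undetected species).
#' @export
sample_multinomial <- function(assemblage, n, seed = NULL) {
  stopifnot(inherits(assemblage, "assemblage"), is_whole(n), n >= 1)
  draw <- function() {
    as.integer(stats::rmultinom(1, size = n, prob = assemblage$p))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Frequency counts of a raw multinomial sample
#' @param counts integer vector of per-species counts (zeros allowed).
#' @return A `freq_counts` object over the detected species.
#' @export
sample_freq_counts <- function(counts) {
  pos <- counts[counts > 0]
  if (length(pos) == 0) stop("no species detected in sample")
  tab <- tabulate(pos)
  keep <- tab > 0
  freq_counts_from_table(which(keep), tab[keep])
}

#' Empirical assemblage from observed frequency counts
#'
#' Treats the observed relative abundances as the true detection
#' probabilities: \eqn{p_i = X_i / n} over the abundance vector implied by
#' the frequency counts. When the spectrum carries an aggregated tail
#' (packaged fixtures record species with \eqn{k \ge 15} as one total),
#' per-species tail abundances are reconstructed with [tail_allocate()].
#'
#' @param fc a [freq_counts()] object, or a fixture from
#'   [richness_fixture()].
#' @param tail_species number of species aggregated in the tail (0 if
#'   none).
#' @param tail_individuals total individuals in the aggregated tail.
#' @param tail_min smallest abundance a tail species may take.
#' @return An `assemblage` object.
#' @export
empirical_assemblage <- function(fc, tail_species = 0,
                                 tail_individuals = 0, tail_min = 15) {
  if (inherits(fc, "richness_fixture")) {
    fx <- fc
    return(empirical_assemblage(fx$freq, tail_species = fx$tail_species,
                                tail_individuals = fx$tail_individuals,
                                tail_min = fx$tail_min))
  }
  stopifnot(inherits(fc, "freq_counts"))
  ks <- multiplicities(fc)
  abund <- rep(ks, times = fc$f)
  if (tail_species > 0) {
    abund <- c(abund, tail_allocate(tail_species, tail_individuals,
                                    tail_min))
  }
  new_assemblage("empirical", length(abund), abund / sum(abund))
}

#' Deterministic tail reconstruction
#'
#' Splits `total` individuals among `n_species` species, each receiving at
#' least `minimum`, with the surplus allocated by geometric-decay weights
#' (ratio 0.8) and a largest-remainder rounding so the sum is exact. Used
#' to expand the aggregated ">= 15" cells of the packaged fixtures into a
#' concrete abundance tail; the rule is deterministic so empirical
#' assemblages are reproducible, and only the tail shape (not any
#' estimator input) depends on it.
#'
#' @param n_species number of tail species.
#' @param total total individuals to distribute.
#' @param minimum minimum abundance per species.
#' @return Integer vector of length `n_species`, non-increasing, summing
#'   to `total`.
#' @export
tail_allocate <- function(n_species, total, minimum = 15) {
  stopifnot(is_whole(n_species), n_species >= 1, is_whole(total))
  if (total < n_species * minimum) {
    stop(sprintf(
      "cannot place %d individuals into %d tail species of at least %d",
      total, n_species, minimum))
  }
  surplus <- total - n_species * minimum
  w <- 0.8^(seq_len(n_species) - 1)
  raw <- surplus * w / sum(w)
  extra <- floor(raw)
  short <- surplus - sum(extra)
  if (short > 0) {
    bump <- order(raw - extra, decreasing = TRUE)[seq_len(short)]
    extra[bump] <- extra[bump] + 1
  }
  sort(as.integer(minimum + extra), decreasing = TRUE)
}

#' Export an assemblage's probability vector as text
#'
#' Two columns, `species_index` and `p`, for reproducibility audits.
#' @param assemblage an `assemblage` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_assemblage <- function(assemblage, path) {
  stopifnot(inherits(assemblage, "assemblage"))
  utils::write.table(
    data.frame(species_index = seq_len(assemblage$S),
               p = assemblage$p),
    path, sep = ",", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Import an assemblage written by [write_assemblage()]
#' @param path input file path.
#' @return An `assemblage` object (model id `"imported"`).
#' @export
read_assemblage <- function(path) {
  d <- utils::read.csv(path)
  new_assemblage("imported", nrow(d), d$p)
}
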