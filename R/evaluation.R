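# Monte Carlo evaluation harness.
#
# For a fixed assemblage and a grid of sample sizes, draws multinomial
# samples, applies every requested estimator (with its asymptotic s.e.
# and log-normal CI), and aggregates the standard benchmarking metrics:
# average estimate, bias, sample s.e., average estimated s.e., RMSE and
# 95% CI coverage against the true S.

#' Run a richness-estimator simulation over a sample-size grid
#'
#' Each replicate draws one multinomial sample from the assemblage using
#' a child seed derived from `(seed, n, replicate)`, so results are
#' independent of execution order and reproducible from the config alone.
#' Replicates on which an estimator is undefined (Chao-Bunge with
#' \eqn{\hat\theta \le 0}) are excluded from that estimator's averages
#' and counted in `failures`; `cb_raw = TRUE` instead averages the raw
#' ratio whatever its sign, mirroring naive batch averaging.
#'
#' @param assemblage an `assemblage` object.
#' @param n_grid integer vector of sample sizes.
#' @param reps number of replicates per sample size.
#' @param estimators estimator ids to evaluate (the default battery is
#'   the five closed-form estimators; the experimental MLE is excluded).
#' @param seed integer master seed.
#' @param level confidence level for coverage.
#' @param cb_raw average raw Chao-Bunge ratios instead of excluding
#'   undefined replicates.
#' @return An `evaluation_table`: a data frame with one row per
#'   `(n, estimator)` and columns `model`, `S`, `n`, `estimator`, `reps`,
#'   `mean_obs_richness`, `average_estimate`, `bias`, `sample_se`,
#'   `average_estimated_se`, `rmse`, `coverage`, `failures`. The run
#'   configuration is attached as attribute `config`.
#' @examples
#' asm <- make_assemblage("homogeneous", S = 200)
#' run_simulation(asm, n_grid = 400, reps = 10, seed = 1)
#' @export
run_simulation <- function(assemblage, n_grid, reps,
                           estimators = c("chao1", "jackknife1",
                                          "chao_bunge", "lb", "gp"),
                           seed, level = 0.95, cb_raw = FALSE) {
  stopifnot(inherits(assemblage, "assemblage"), reps >= 1,
            all(is_whole(n_grid)), all(n_grid >= 1))
  estimators <- match.arg(estimators,
                          c("chao1", "jackknife1", "chao_bunge", "lb", "gp"),
                          several.ok = TRUE)
  S <- assemblage$S
  rows <- list()
  for (n in n_grid) {
    pts <- matrix(NA_real_, nrow = reps, ncol = length(estimators),
                  dimnames = list(NULL, estimators))
    ses <- pts
    covered <- matrix(NA, nrow = reps, ncol = length(estimators),
                      dimnames = list(NULL, estimators))
    obs <- numeric(reps)
    for (r in seq_len(reps)) {
      counts <- sample_multinomial(assemblage, n,
                                   seed = child_seed(seed, n, r))
      fc <- sample_freq_counts(counts)
      obs[r] <- fc$S_obs
      for (id in estimators) {
        est <- if (id == "chao_bunge") {
          estimate_chao_bunge(fc, se = TRUE, level = level,
                              allow_nonpositive_theta = cb_raw)
        } else {
          richness_estimator(id)(fc, se = TRUE, level = level)
        }
        pts[r, id] <- est$point
        ses[r, id] <- est$se
        if (!is.na(est$ci[["lower"]])) {
          covered[r, id] <- est$ci[["lower"]] <= S && S <= est$ci[["upper"]]
        }
      }
    }
    for (id in estimators) {
      x <- pts[, id]
      ok <- !is.na(x)
      rows[[length(rows) + 1]] <- data.frame(
        model = assemblage$model, S = S, n = n, estimator = id,
        reps = reps,
        mean_obs_richness = mean(obs),
        average_estimate = if (any(ok)) mean(x[ok]) else NA_real_,
        bias = if (any(ok)) mean(x[ok]) - S else NA_real_,
        sample_se = if (sum(ok) > 1) stats::sd(x[ok]) else NA_real_,
        average_estimated_se = mean(ses[ok, id], na.rm = TRUE),
        rmse = if (any(ok)) sqrt(mean((x[ok] - S)^2)) else NA_real_,
        coverage = mean(covered[, id], na.rm = TRUE),
        failures = sum(!ok),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(model = assemblage$model, S = S,
                              assemblage_seed = assemblage$seed,
                              cv = assemblage$cv, n_grid = n_grid,
                              reps = reps, estimators = estimators,
                              seed = seed, level = level, cb_raw = cb_raw)
  class(out) <- c("evaluation_table", "data.frame")
  out
}

#' Bias/RMSE sweep over sample size
#'
#' Convenience wrapper over [run_simulation()] for an even grid of sample
#' sizes, used to trace how bias and RMSE shrink as sampling effort
#' grows.
#'
#' @inheritParams run_simulation
#' @param n_min,n_max,n_step grid of sample sizes
#'   `seq(n_min, n_max, by = n_step)`.
#' @return An `evaluation_table`.
#' @export
bias_rmse_curve <- function(assemblage, n_min, n_max, n_step, reps,
                            estimators = c("chao1", "jackknife1",
                                           "chao_bunge", "lb", "gp"),
                            seed, level = 0.95, cb_raw = FALSE) {
  run_simulation(assemblage, seq(n_min, n_max, by = n_step), reps,
                 estimators, seed, level = level, cb_raw = cb_raw)
}

metric_cols <- c("average_estimate", "bias", "sample_se",
                 "average_estimated_se", "rmse", "coverage")

#' Render an evaluation table
#'
#' @param table an `evaluation_table` from [run_simulation()].
#' @param format `"tsv"`, `"markdown"` or `"json"`. The text formats
#'   round estimates to 1 decimal and coverage to 2, matching standard
#'   reporting precision; JSON keeps full precision and round-trips via
#'   [parse_evaluation_json()].
#' @return A single character string.
#' @export
summarize_evaluation <- function(table, format = c("tsv", "markdown",
                                                   "json")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "evaluation_table"), nrow(table) >= 0)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      list(config = attr(table, "config"),
           rows = as.data.frame(unclass(table),
                                stringsAsFactors = FALSE)),
      auto_unbox = TRUE, digits = NA, na = "null"
    )))
  }
  d <- as.data.frame(table)
  for (col in setdiff(metric_cols, "coverage")) {
    d[[col]] <- round(d[[col]], 1)
  }
  d$coverage <- round(d$coverage, 2)
  d$mean_obs_richness <- round(d$mean_obs_richness, 1)
  if (format == "tsv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
    return(paste(out, collapse = "\n"))
  }
  # markdown
  cells <- rbind(colnames(d), format(as.matrix(d), trim = TRUE))
  lines <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                              " |"))
  sep <- paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|")
  paste(c(lines[1], sep, lines[-1]), collapse = "\n")
}

#' Rebuild an evaluation table from its JSON rendering
#' @param json a JSON string produced by
#'   `summarize_evaluation(format = "json")`.
#' @return An `evaluation_table`.
#' @export
parse_evaluation_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  out <- as.data.frame(obj$rows, stringsAsFactors = FALSE)
  cfg <- obj$config
  cfg$n_grid <- as.numeric(cfg$n_grid)
  attr(out, "config") <- cfg
  class(out) <- c("evaluation_table", "data.frame")
  out
}
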