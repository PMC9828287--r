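# Packaged frequency-count fixtures.
#
# Three published frequency-count rows ship with the package as plain CSV
# under inst/extdata: vascular plants (southern Appalachians), butterflies
# (Malaya) and ground-dwelling invertebrates (Tasmania). Each file lists
# f_1..f_14 verbatim plus one aggregated "15+" cell; the total number of
# individuals is recorded in the header so the aggregated tail can be
# reconstructed deterministically when a full abundance vector is needed.

fixture_files <- c(
  vascular = "vascular_plants.csv",
  butterfly = "malayan_butterflies.csv",
  invertebrate = "tasmanian_invertebrates.csv"
)

fixture_totals <- c(vascular = 1008, butterfly = 9031, invertebrate = 2050)

#' Load a packaged frequency-count fixture
#'
#' @param name one of `"vascular"`, `"butterfly"`, `"invertebrate"`.
#' @return An object of class `richness_fixture`: a list with `name`,
#'   `freq` (a [freq_counts()] object over the verbatim k = 1..14 cells),
#'   `tail_species`, `tail_individuals`, `tail_min` (15), and `n_total`.
#' @examples
#' fx <- richness_fixture("vascular")
#' fx$freq$S_obs + fx$tail_species  # 188 species in total
#' @export
richness_fixture <- function(name = c("vascular", "butterfly",
                                      "invertebrate")) {
  name <- match.arg(name)
  path <- system.file("extdata", fixture_files[[name]], package = "richGP")
  if (!nzchar(path)) stop("fixture data not found; is richGP installed?")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines[-1], ",", fixed = TRUE)  # drop header row
  keys <- vapply(parts, `[`, "", 1)
  vals <- as.numeric(vapply(parts, `[`, "", 2))
  is_tail <- grepl("\\+$", keys)
  fc <- freq_counts_from_table(as.integer(keys[!is_tail]), vals[!is_tail])
  tail_min <- as.integer(sub("\\+$", "", keys[is_tail][1]))
  n_total <- fixture_totals[[name]]
  structure(
    list(name = name, freq = fc,
         tail_species = as.integer(sum(vals[is_tail])),
         tail_individuals = as.integer(n_total - fc$n),
         tail_min = tail_min, n_total = n_total),
    class = "richness_fixture"
  )
}

#' @export
print.richness_fixture <- function(x, ...) {
  cat(sprintf(
    "Fixture '%s': %d species (%d in aggregated tail), %d individuals\n",
    x$name, as.integer(x$freq$S_obs + x$tail_species), x$tail_species,
    x$n_total))
  invisible(x)
}

#' Frequency counts of a fixture including its reconstructed tail
#'
#' Expands the aggregated tail with [tail_allocate()] and returns the
#' full frequency-count object (f_1..f_14 verbatim; the tail multiplicity
#' pattern is the deterministic reconstruction, flagged as such by the
#' fixture documentation).
#'
#' @param fixture a [richness_fixture()] object.
#' @return A `freq_counts` object with `S_obs` and `n` equal to the
#'   fixture's published totals.
#' @export
fixture_freq_counts <- function(fixture) {
  stopifnot(inherits(fixture, "richness_fixture"))
  ks <- multiplicities(fixture$freq)
  abund <- rep(ks, times = fixture$freq$f)
  if (fixture$tail_species > 0) {
    abund <- c(abund, tail_allocate(fixture$tail_species,
                                    fixture$tail_individuals,
                                    fixture$tail_min))
  }
  freq_counts(abund)
}

#' Copy a fixture file to a destination
#'
#' @param name fixture name; unknown names raise an error listing the
#'   valid ones.
#' @param dest destination file path.
#' @return `dest`, invisibly.
#' @export
export_fixture <- function(name, dest) {
  if (!name %in% names(fixture_files)) {
    stop(sprintf("unknown fixture '%s'; valid names: %s", name,
                 paste(names(fixture_files), collapse = ", ")))
  }
  src <- system.file("extdata", fixture_files[[name]], package = "richGP")
  file.copy(src, dest, overwrite = TRUE)
  invisible(dest)
}
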