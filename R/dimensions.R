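# Category inventories for the five annotation dimensions. Order within each
# vector is the canonical display order; the first default_* entry below is
# what an event receives when its context gives no explicit signal.

#' Annotation dimensions and their category inventories
#'
#' The scheme annotates every bio-event along five mutually exclusive
#' dimensions:
#'
#' * **KT** (Knowledge Type): the general information content of the event —
#'   `Investigation`, `Observation`, `Analysis`, `Method`, `Fact` or `Other`
#'   (default).
#' * **CL** (Certainty Level): `L3` (no expressed uncertainty, default),
#'   `L2` (slight hedging, or "frequently but not always"), `L1`
#'   (considerable speculation, or rare occurrence).
#' * **Polarity**: `Positive` (default) or `Negative` (explicitly negated).
#' * **Manner**: expressed rate/level/strength of the event — `High`, `Low`
#'   or `Neutral` (default).
#' * **Source**: attribution to the `Current` study (default) or to `Other`
#'   (previous) work.
#'
#' @return `mk_dimensions()` returns a named list of character vectors, one
#'   per dimension; `mk_dimension_values(dimension)` returns the category
#'   inventory of one dimension.
#' @examples
#' mk_dimensions()
#' mk_dimension_values("CL")
#' @export
mk_dimensions <- function() {
  list(
    KT       = c("Other", "Observation", "Analysis", "Fact", "Investigation", "Method"),
    CL       = c("L3", "L2", "L1"),
    Polarity = c("Positive", "Negative"),
    Manner   = c("Neutral", "High", "Low"),
    Source   = c("Current", "Other")
  )
}

#' @param dimension One of `"KT"`, `"CL"`, `"Polarity"`, `"Manner"`,
#'   `"Source"`.
#' @rdname mk_dimensions
#' @export
mk_dimension_values <- function(dimension) {
  dims <- mk_dimensions()
  if (!dimension %in% names(dims)) {
    abort(paste0("Unknown dimension '", dimension, "'; expected one of: ",
                 paste(names(dims), collapse = ", ")))
  }
  dims[[dimension]]
}

# lower-case column names used in the events table, keyed by dimension label
mk_dimension_columns <- function() {
  c(KT = "kt", CL = "cl", Polarity = "polarity",
    Manner = "manner", Source = "source")
}

#' Default meta-knowledge value tuple
#'
#' Every dimension has a designated default category, assigned when the
#' textual context of an event carries no explicit clue: KT = `Other`,
#' CL = `L3`, Polarity = `Positive`, Manner = `Neutral`, Source = `Current`.
#' Defaults never require a clue expression, so a clue-free event annotated
#' with this tuple is always valid.
#'
#' @return A one-row tibble with columns `kt`, `cl`, `polarity`, `manner`,
#'   `source`.
#' @examples
#' default_metaknowledge()
#' @export
default_metaknowledge <- function() {
  tibble(kt = "Other", cl = "L3", polarity = "Positive",
         manner = "Neutral", source = "Current")
}

#' Round a percentage the way the distribution tables do
#'
#' All percentage columns produced by the statistics functions share this one
#' rounding rule: round half away from zero ("half up" for the non-negative
#' values that occur here) at the requested number of decimals. A single
#' shared function guarantees every table changes consistently if the rule
#' ever changes.
#'
#' @param x Numeric vector of percentages (or any numbers).
#' @param digits Decimal places to keep (default 1, the convention used in
#'   the distribution tables).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' mk_round_pct(c(31.25, 31.34, 31.35))
#' @export
mk_round_pct <- function(x, digits = 1) {
  p <- 10^digits
  # tiny epsilon guards against binary-float representations of exact halves
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# is value `v` the default for dimension `d`?
is_default_value <- function(d, v) {
  defaults <- c(KT = "Other", CL = "L3", Polarity = "Positive",
                Manner = "Neutral", Source = "Current")
  v == defaults[[d]]
}
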