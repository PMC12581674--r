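#' Default SOFA scoring grid
#'
#' The standard six-organ Sequential Organ Failure Assessment grid, each
#' organ scored 0-4. Shipped as a plain configurable list so local scoring
#' conventions (e.g. alternative cardiovascular definitions) can be
#' substituted; the same grid is available as YAML at
#' `system.file("extdata", "sofa_grid.yaml", package = "akirank")`.
#'
#' Organs and inputs: `respiration` (PaO2/FiO2, mmHg, lower worse),
#' `coagulation` (platelets, 10^3/uL, lower worse), `liver` (bilirubin,
#' mg/dL, higher worse), `cardiovascular` (ordinal category 0-4 encoding
#' MAP/vasopressor use), `cns` (Glasgow Coma Scale, lower worse), `renal`
#' (creatinine, mg/dL, higher worse).
#'
#' @return Named list; each element has `direction` (`"low"` or `"high"`,
#'   or `"category"`) and `cuts`, the four thresholds for subscores 1-4.
#' @export
sofa_score_table <- function() {
  list(
    respiration = list(direction = "low", cuts = c(400, 300, 200, 100)),
    coagulation = list(direction = "low", cuts = c(150, 100, 50, 20)),
    liver = list(direction = "high", cuts = c(1.2, 2.0, 6.0, 12.0)),
    cardiovascular = list(direction = "category", cuts = 0:4),
    cns = list(direction = "low", cuts = c(15, 13, 10, 6)),
    renal = list(direction = "high", cuts = c(1.2, 2.0, 3.5, 5.0))
  )
}

sofa_subscore <- function(value, rule) {
  if (is.na(value)) return(NA_integer_)
  if (rule$direction == "category") {
    if (!value %in% 0:4) stop_config("category subscore input must be 0..4")
    return(as.integer(value))
  }
  cuts <- rule$cuts
  score <- if (rule$direction == "high") sum(value > cuts)
  else sum(value < cuts)
  as.integer(score)
}

#' Daily SOFA score
#'
#' Sum of the six organ subscores (0-24) from the configurable grid.
#' A missing organ input is scored 0 and flagged, the common ICU-trial
#' convention when a system was not assessed; set `missing = "carry"` and
#' supply `previous` to carry the prior day's subscore forward instead.
#'
#' @param organ_inputs Named list/vector of the six organ inputs
#'   (`respiration`, `coagulation`, `liver`, `cardiovascular`, `cns`,
#'   `renal`); missing entries allowed.
#' @param score_table Grid from [sofa_score_table()].
#' @param missing `"zero"` (default) or `"carry"`.
#' @param previous Previous day's subscores (named), used for `"carry"`.
#' @return List with `total` (0-24), `subscores` (named integer vector),
#'   and `missing_organs` (character).
#' @export
#' @examples
#' sofa_daily(list(respiration = 450, coagulation = 200, liver = 0.8,
#'                 cardiovascular = 0, cns = 15, renal = 0.9))$total  # 0
sofa_daily <- function(organ_inputs, score_table = sofa_score_table(),
                       missing = c("zero", "carry"), previous = NULL) {
  missing <- match.arg(missing)
  organs <- names(score_table)
  sub <- stats::setNames(integer(length(organs)), organs)
  flagged <- character(0)
  for (org in organs) {
    val <- organ_inputs[[org]]
    s <- if (is.null(val)) NA_integer_ else sofa_subscore(val, score_table[[org]])
    if (is.na(s)) {
      flagged <- c(flagged, org)
      s <- if (missing == "carry" && !is.null(previous) &&
               !is.na(previous[org])) previous[[org]] else 0L
    }
    sub[org] <- s
  }
  list(total = sum(sub), subscores = sub, missing_organs = flagged)
}

#' @rdname sofa_score_table
#' @param path YAML file encoding the grid; defaults to the one shipped
#'   with the package.
#' @export
sofa_table_from_yaml <- function(path = system.file(
  "extdata", "sofa_grid.yaml", package = "akirank")) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x) list(direction = x$direction,
                               cuts = as.numeric(x$cuts)))
}
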