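#' Kinetic parameter sets for hERG gating models
#'
#' A `kinetic_parameters` object bundles the kinetic rate coefficients of a
#' gating model (rate prefactors in ms^-1 and voltage slopes in mV^-1, held on
#' their natural scale) together with the maximal conductance `g` (in units of
#' 0.1 uS, the scale in which the published values are quoted).
#'
#' @param values named numeric vector of strictly positive kinetic parameters.
#'   Length 8 for the four-state (Beattie-type) model (`p1..p8`) or 14 for the
#'   five-state (Wang-type) model (`kb`, `kf`, `q1..q12`).
#' @param g maximal conductance, strictly positive, in units of 0.1 uS.
#' @param model label for the model family the set belongs to.
#' @return an object of class `kinetic_parameters`.
#' @seealso [beattie_parameters()], [wang_parameters()], [parameter_ranges()]
#' @export
kinetic_parameters <- function(values, g, model = "custom") {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("'values' must have unique names")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("kinetic parameters must be strictly positive and finite")
  if (!is.numeric(g) || length(g) != 1 || !is.finite(g) || g <= 0)
    stop("'g' must be a single positive number")
  structure(list(values = values, g = g, model = model),
            class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Kinetic parameters (", x$model, " model)\n", sep = "")
  print(signif(c(x$values, g = x$g), 4))
  invisible(x)
}

# Printed default values and the scale factor of each row of the published
# parameter table.  Values are stored here exactly as printed; the natural
# scale is value * scale.
.beattie_table <- data.frame(
  name  = c("g", paste0("p", 1:8)),
  value = c(2.44, 1.68, 8.06, 4.34, 4.07, 9.07, 2.67, 7.32, 3.22),
  scale = c(1e-1, 1e-4, 1e-2, 1e-5, 1e-2, 1e-2, 1e-2, 1e-3, 1e-2),
  unit  = c("uS", rep(c("ms^-1", "mV^-1"), 4)),
  lower = c(NA, 1.39, 1.08, 2.77, 2.48, 6.40, 2.18, 7.07, 2.89),
  upper = c(NA, 12.9, 8.49, 32.3, 4.56, 19.9, 3.87, 10.9, 3.39),
  stringsAsFactors = FALSE
)

.wang_table <- data.frame(
  name  = c("g", "kb", "kf", paste0("q", 1:12)),
  value = c(2.11, 0.67, 1.31, 1.24, 1.56, 0.04, 10.9, 0.24, 0.0001,
            3.15, 3.99, 5.75, 2.89, 0.28, 10.7),
  scale = c(1e-1, 1e-2, 1e-2, 1e-1, 1e-2, 1e-2, 1e-2, 1e-2, 1e-2,
            1e-4, 1e-2, 1e-3, 1e-2, 1e-2, 1e-2),
  unit  = c("uS", "ms^-1", "ms^-1",
            rep(c("ms^-1", "mV^-1"), 6)),
  lower = c(NA, 0.67, 1.31, 1.24, 1.55, 0.03, 0.0001, 0.23, 0.0001,
            1.29, 2.97, 3.55, 2.89, 0.007, 1.16),
  upper = c(NA, 99993, 99550, 1.81, 2.06, 1.02, 10.9, 364, 6.44,
            7.69, 3.99, 5.75, 3.34, 1458, 11.8),
  stringsAsFactors = FALSE
)

.table_to_parameters <- function(tab, model) {
  kin <- tab[tab$name != "g", ]
  kinetic_parameters(values = stats::setNames(kin$value * kin$scale, kin$name),
                     g = tab$value[tab$name == "g"] * tab$scale[tab$name == "g"] / 1e-1,
                     model = model)
}

#' Default published parameter set for the four-state (Beattie-type) model
#'
#' Room-temperature default values `p1..p8` (natural scale, ms^-1 / mV^-1)
#' and conductance `g` (0.1 uS units).
#' @return a [kinetic_parameters()] object.
#' @export
beattie_parameters <- function() .table_to_parameters(.beattie_table, "beattie")

#' Default published parameter set for the five-state (Wang-type) model
#'
#' Room-temperature default values `kb`, `kf`, `q1..q12` (natural scale) and
#' conductance `g` (0.1 uS units).
#' @return a [kinetic_parameters()] object.
#' @export
wang_parameters <- function() .table_to_parameters(.wang_table, "wang")

#' Parameter ranges for sensitivity-based and sampling-based designs
#'
#' Elementwise lower/upper bounds aligned with a [kinetic_parameters()] vector,
#' on the natural scale.  The shipped defaults are the ranges obtained from
#' real-data fits under a set of calibration protocols, as quoted alongside
#' the default parameter values.
#'
#' @param lower,upper named numeric vectors, strictly positive,
#'   `lower <= upper` elementwise.
#' @return an object of class `parameter_ranges`.
#' @export
parameter_ranges <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == length(upper))
  if (!identical(names(lower), names(upper)))
    stop("'lower' and 'upper' must have identical names")
  if (any(lower <= 0) || any(upper <= 0)) stop("bounds must be strictly positive")
  if (any(lower > upper)) stop("'lower' must be <= 'upper' elementwise")
  structure(list(lower = lower, upper = upper), class = "parameter_ranges")
}

.table_to_ranges <- function(tab) {
  kin <- tab[tab$name != "g", ]
  parameter_ranges(lower = stats::setNames(kin$lower * kin$scale, kin$name),
                   upper = stats::setNames(kin$upper * kin$scale, kin$name))
}

#' @rdname parameter_ranges
#' @export
beattie_ranges <- function() .table_to_ranges(.beattie_table)

#' @rdname parameter_ranges
#' @export
wang_ranges <- function() .table_to_ranges(.wang_table)

#' Read and write parameter tables
#'
#' Plain tab-delimited text with columns `name`, `value`, `unit`, `lower`,
#' `upper`, mirroring the published parameter table: `value`, `lower` and
#' `upper` are on the printed scale and the `unit` column carries the scale
#' factor as a `<scale>*<unit>` string (for example `1e-4*ms^-1`).  The reader
#' applies the printed scale factors exactly, so the shipped default files
#' reproduce the published table bit-for-bit on round-trip.
#'
#' @param path file path.
#' @return `read_parameter_table()`: a list with elements `parameters`
#'   (a [kinetic_parameters()] object) and `ranges` (a [parameter_ranges()]
#'   object, or `NULL` when no bounds are present).
#' @export
read_parameter_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("name", "value", "unit", "lower", "upper")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns ", paste(need, collapse = ", "))
  parts <- strsplit(tab$unit, "*", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop("malformed unit field at row(s) ", paste(bad, collapse = ", "))
  tab$scale <- vapply(parts, function(z) as.numeric(z[[1]]), numeric(1))
  tab$unit <- vapply(parts, `[[`, character(1), 2)
  model <- if (all(paste0("p", 1:8) %in% tab$name)) "beattie"
           else if (all(paste0("q", 1:12) %in% tab$name)) "wang"
           else "custom"
  params <- .table_to_parameters(tab, model)
  ranges <- if (all(is.na(tab$lower[tab$name != "g"]))) NULL else .table_to_ranges(tab)
  list(parameters = params, ranges = ranges)
}

#' @param tab a data frame with columns `name`, `value`, `scale`, `unit`,
#'   `lower`, `upper` (printed-scale values), as returned by
#'   [default_parameter_table()].
#' @rdname read_parameter_table
#' @export
write_parameter_table <- function(tab, path) {
  out <- data.frame(name = tab$name, value = tab$value,
                    unit = paste0(format(tab$scale, scientific = TRUE), "*", tab$unit),
                    lower = tab$lower, upper = tab$upper,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published parameter table in printed-scale form
#'
#' @param model `"beattie"` or `"wang"`.
#' @return data frame with columns `name`, `value`, `scale`, `unit`, `lower`,
#'   `upper`; `value * scale` is the natural-scale value.
#' @export
default_parameter_table <- function(model = c("beattie", "wang")) {
  model <- match.arg(model)
  if (model == "beattie") .beattie_table else .wang_table
}
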