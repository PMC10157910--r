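# Age-dependent background mortality: synthetic Gompertz life tables, CSV IO,
# and hazard-scale adjustment of annual death probabilities.

validate_life_table <- function(age, qx) {
  if (length(age) != length(qx) || !length(age))
    stop("life table: 'age' and 'qx' must be non-empty and equally long")
  if (any(!is.finite(age)) || any(!is.finite(qx)))
    stop("life table: non-finite entries")
  if (any(diff(age) != 1))
    stop("life table: ages must be contiguous one-year steps")
  if (any(qx < 0 | qx > 1))
    stop("life table: qx outside [0, 1]")
  if (qx[length(qx)] != 1)
    stop("life table: qx at the final age must be 1 (forced terminal death)")
  invisible(TRUE)
}

new_life_table <- function(age, qx) {
  validate_life_table(age, qx)
  structure(data.frame(age = as.integer(age), qx = as.numeric(qx)),
            class = c("sarco_lifetable", "data.frame"))
}

#' Synthesise a Gompertz life table anchored at one printed probability
#'
#' Builds an annual life table from a Gompertz hazard anchored so the annual
#' death probability at `anchor_age` equals `q_anchor` exactly:
#' `h(a) = -log(1 - q_anchor) * exp(slope * (a - anchor_age))`,
#' `qx(a) = 1 - exp(-h(a))` capped at 1, with `qx(max_age)` forced to 1.
#' The default slope 0.085/yr corresponds to the canonical human mortality
#' doubling time of about 8 years.
#'
#' @param q_anchor Annual death probability at the anchor age, in (0, 1).
#' @param anchor_age Age (years) at which `q_anchor` applies.
#' @param slope Gompertz log-hazard slope per year of age (>= 0).
#' @param max_age Final age of the table; everyone alive there dies.
#' @return A `sarco_lifetable` data frame with columns `age`, `qx`.
#' @examples
#' lt <- gompertz_life_table()
#' lt$qx[lt$age == 60]  # 0.0095
#' @export
gompertz_life_table <- function(q_anchor = 0.0095, anchor_age = 60,
                                slope = 0.085, max_age = 110) {
  if (!is.numeric(q_anchor) || q_anchor <= 0 || q_anchor >= 1)
    stop("gompertz_life_table: q_anchor must lie in (0, 1)")
  if (slope < 0) stop("gompertz_life_table: slope must be >= 0")
  if (max_age <= anchor_age)
    stop("gompertz_life_table: max_age must exceed anchor_age")
  age <- seq.int(anchor_age, max_age)
  h <- -log(1 - q_anchor) * exp(slope * (age - anchor_age))
  qx <- pmin(1 - exp(-h), 1)
  qx[length(qx)] <- 1
  new_life_table(age, qx)
}

#' Read a life table from CSV
#'
#' Expects a two-column CSV `age,qx` (header optional) with contiguous
#' one-year ages, probabilities in `[0, 1]` and terminal `qx = 1`.
#'
#' @param path CSV file path.
#' @return A `sarco_lifetable`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("read_life_table: no such file: ", path)
  first <- utils::read.csv(path, header = FALSE, nrows = 1,
                           stringsAsFactors = FALSE)
  has_header <- any(is.na(suppressWarnings(as.numeric(unlist(first)))))
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("read_life_table: need two columns (age, qx)")
  new_life_table(as.numeric(df[[1]]), as.numeric(df[[2]]))
}

#' Write a life table to CSV
#'
#' @param lt A `sarco_lifetable`.
#' @param path Output CSV path (columns `age,qx`).
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "sarco_lifetable"))
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Annual death probability at a given age; errors outside the table range.
lt_qx <- function(lt, age) {
  i <- age - lt$age[1L] + 1L
  if (any(i < 1L | i > nrow(lt)))
    stop("life table: age ", paste(age[i < 1L | i > nrow(lt)], collapse = ", "),
         " outside table range ", lt$age[1L], "-", lt$age[nrow(lt)])
  lt$qx[i]
}

#' Apply a hazard ratio / relative risk to an annual death probability
#'
#' Multipliers are applied on the hazard scale,
#' `q' = 1 - (1 - q)^multiplier`, which keeps the result in `[0, 1]` at any
#' age (direct probability multiplication would not). For small `q` this
#' agrees with `multiplier * q` to second order. Combined excess risks (e.g.
#' sarcopenia hazard ratio times first-year fracture relative risk) multiply
#' on the same scale.
#'
#' @param q Annual death probability in `[0, 1]` (vectorised).
#' @param hazard_multiplier Positive hazard multiplier.
#' @return Adjusted probability, always in `[0, 1]`.
#' @examples
#' adjusted_death_prob(0.0095, 1.6)
#' @export
adjusted_death_prob <- function(q, hazard_multiplier) {
  if (any(q < 0 | q > 1)) stop("adjusted_death_prob: q outside [0, 1]")
  if (any(hazard_multiplier <= 0))
    stop("adjusted_death_prob: hazard_multiplier must be > 0")
  1 - (1 - q)^hazard_multiplier
}
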