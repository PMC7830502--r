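#' IUCN-style risk categories
#'
#' Ordered factor levels LC < NT < VU < EN < CR < EX. Note that "EX"
#' here is a projected-status label under a criterion-A3-style
#' assessment (100% projected occupancy loss), not a formal extinction
#' declaration.
#'
#' @param x character vector of category codes.
#' @return ordered factor.
#' @export
risk_category <- function(x) {
  factor(x, levels = c("LC", "NT", "VU", "EN", "CR", "EX"), ordered = TRUE)
}

# Category cut-offs on projected AOO loss percentage. Boundary values are
# assigned precautionarily (an exact boundary takes the more threatened
# category); gains (loss <= 0) are always LC.
RISK_BOUNDS <- c(NT = 15, VU = 30, EN = 50, CR = 80, EX = 100)

#' Classify projected occupancy loss into a risk category
#'
#' Projected AOO loss percentage maps to: EX at exactly 100% loss, CR
#' for loss > 80, EN for loss > 50, VU for loss > 30, NT for loss >= 15,
#' LC below 15 (including all gains, which enter as loss <= 0). The
#' mapping is total and monotone non-decreasing in loss.
#'
#' @param loss_pct numeric loss percentage(s), at most 100; gains are
#'   negative.
#' @return [risk_category] vector.
#' @export
classify_risk <- function(loss_pct) {
  if (any(!is.finite(loss_pct)) || any(loss_pct > 100))
    stop("loss percentage must be finite and at most 100")
  out <- character(length(loss_pct))
  out[loss_pct < RISK_BOUNDS[["NT"]]] <- "LC"
  out[loss_pct >= RISK_BOUNDS[["NT"]]] <- "NT"
  out[loss_pct > RISK_BOUNDS[["VU"]]] <- "VU"
  out[loss_pct > RISK_BOUNDS[["EN"]]] <- "EN"
  out[loss_pct > RISK_BOUNDS[["CR"]]] <- "CR"
  out[loss_pct == RISK_BOUNDS[["EX"]]] <- "EX"
  risk_category(out)
}

#' Compare proposed status against the current Red List status
#'
#' @param current,proposed [risk_category] values (or codes).
#' @return `"up-listed"`, `"down-listed"` or `"unchanged"` per element.
#' @export
compare_status <- function(current, proposed) {
  current <- risk_category(as.character(current))
  proposed <- risk_category(as.character(proposed))
  ifelse(is.na(current) | is.na(proposed), "unknown",
         ifelse(proposed > current, "up-listed",
                ifelse(proposed < current, "down-listed", "unchanged")))
}

#' Assemble a per-species extinction-risk assessment
#'
#' Applies [classify_risk()] and [compare_status()] to each scenario's
#' projected AOO change and returns a tidy table, one row per
#' combination of climate scenario, threshold rule and dispersal
#' scenario. Scenarios are reported side by side, never merged.
#'
#' @param species species label.
#' @param current_status current Red List code (or `NA` for unknown;
#'   proposed categories are still computed, with the listing change
#'   marked `"unknown"`).
#' @param aoo_results data.frame with columns `scenario`,
#'   `threshold_rule`, `dispersal`, `change_pct` (and optionally
#'   `cells_current`, `cells_future`).
#' @param n_records number of occurrence records (reported).
#' @param trend population trend label (reported).
#' @return object of class `risk_assessment`: data.frame with the input
#'   columns plus `loss_pct`, `proposed_status`, `listing_change`.
#' @export
assess <- function(species, current_status, aoo_results, n_records = NA,
                   trend = NA_character_) {
  if (!nrow(aoo_results)) stop("no scenario results to assess")
  loss <- pmax(0, -aoo_results$change_pct)
  proposed <- classify_risk(loss)
  change <- if (is.na(current_status)) rep("unknown", length(loss))
  else compare_status(rep(current_status, length(loss)), proposed)
  out <- data.frame(species = species, n_records = n_records,
                    current_status = as.character(current_status),
                    trend = trend,
                    aoo_results,
                    loss_pct = loss,
                    proposed_status = as.character(proposed),
                    listing_change = change,
                    row.names = NULL)
  class(out) <- c("risk_assessment", "data.frame")
  out
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("Extinction-risk assessment: %s (current status %s)\n",
              x$species[1], x$current_status[1]))
  cols <- intersect(c("scenario", "threshold_rule", "dispersal",
                      "change_pct", "loss_pct", "proposed_status",
                      "listing_change"), names(x))
  print.data.frame(x[cols], row.names = FALSE, digits = 4)
  cat("Note: 'EX' is a projected A3-style status label, not a formal",
      "extinction declaration.\n")
  invisible(x)
}

#' Write assessment rows to CSV
#'
#' Column layout mirrors a standard status-change report:
#' `species,n_records,current_status,trend,scenario,threshold_rule,dispersal,aoo_change_pct,proposed_status,listing_change`.
#' @param assessments one `risk_assessment` or a list of them.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_assessment <- function(assessments, path) {
  if (inherits(assessments, "risk_assessment"))
    assessments <- list(assessments)
  df <- do.call(rbind, lapply(assessments, function(a) {
    data.frame(species = a$species, n_records = a$n_records,
               current_status = a$current_status, trend = a$trend,
               scenario = a$scenario, threshold_rule = a$threshold_rule,
               dispersal = a$dispersal, aoo_change_pct = a$change_pct,
               proposed_status = a$proposed_status,
               listing_change = a$listing_change)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
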