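#' Percent reduction in forest loss attributable to protection
#'
#' `100 * (loss_control - loss_pa) / loss_control`; positive when protected
#' cells lost less forest than their matched controls, negative when they
#' lost more.  When control loss is exactly zero the ratio is undefined and
#' the absolute difference `loss_control - loss_pa` is returned instead,
#' flagged via attribute `"absolute_difference"`.
#'
#' @param loss_pa Mean loss in protected cells (any consistent unit).
#' @param loss_control Mean loss in matched control cells (same unit).
#' @return Percent reduction (or flagged absolute difference).
#' @export
percent_reduction <- function(loss_pa, loss_control) {
  if (loss_control == 0) {
    out <- loss_control - loss_pa
    attr(out, "absolute_difference") <- TRUE
    return(out)
  }
  100 * (loss_control - loss_pa) / loss_control
}

# Mean loss (%) of a set of cell ids, NA when empty.
.mean_loss_pct <- function(loss, ids) {
  l <- loss$loss[match(ids, loss$cell_id)]
  l <- l[!is.na(l)]
  if (!length(l)) return(NA_real_)
  100 * mean(l)
}

#' Effectiveness report across aggregation levels
#'
#' Combines loss accounting, matching and model estimates into one table:
#' a national row (national pairs), one row per region (submatching pairs
#' by default — the procedure that yields the best regional covariate
#' balance), one row per protected area, and one row per IUCN category.
#' Loss columns are percentages of cell area; `percent_reduction` compares
#' protected cells with their matched controls.  Model fits, where
#' supplied, contribute the protection coefficient and its significance.
#'
#' @param landscape A landscape data frame.
#' @param loss A [compute_loss()] table.
#' @param national_pairs `"matched_pairs"` from [match_national()].
#' @param regional_pairs Named list of per-region pairs (one matching
#'   procedure, default submatching).
#' @param fits Optional named list of `"outcome_fit"` objects: `national`
#'   plus one per region; rows without a fit carry loss columns only.
#' @return A data frame of class `"effectiveness_report"`: `level`,
#'   `group`, `n_pa_cells`, `loss_pa_pct`, `loss_control_pct`,
#'   `loss_unprotected_pct`, `percent_reduction`, `coefficient`, `stars`.
#' @export
build_report <- function(landscape, loss, national_pairs,
                         regional_pairs = NULL, fits = NULL) {
  .assert_landscape(landscape)
  unprot_ids <- landscape$cell_id[!landscape$protected]
  loss_unprot <- .mean_loss_pct(loss, unprot_ids)
  fit_of <- function(key) {
    f <- fits[[key]]
    if (is.null(f)) c(coefficient = NA_real_, stars = NA_character_)
    else c(coefficient = f$coefficient, stars = f$stars)
  }
  row_for <- function(level, group, pa_ids, pairs, unprot_pct, fitkey) {
    fv <- fit_of(fitkey)
    data.frame(level = level, group = group,
               n_pa_cells = length(pa_ids),
               loss_pa_pct = .mean_loss_pct(loss, pa_ids),
               loss_control_pct = if (!is.null(pairs) && nrow(pairs)) {
                 .mean_loss_pct(loss, pairs$control_id)
               } else NA_real_,
               loss_unprotected_pct = unprot_pct,
               percent_reduction = NA_real_,
               coefficient = as.numeric(fv[["coefficient"]]),
               stars = fv[["stars"]],
               stringsAsFactors = FALSE)
  }
  rows <- list()
  pa_ids_all <- landscape$cell_id[landscape$protected]
  rows[["national"]] <- row_for("national", "national", pa_ids_all,
                                national_pairs, loss_unprot, "national")
  for (r in sort(unique(landscape$region_id))) {
    in_r <- landscape$region_id == r
    pa_r <- landscape$cell_id[in_r & landscape$protected]
    if (!length(pa_r)) next
    up_r <- .mean_loss_pct(loss, landscape$cell_id[in_r &
                                                     !landscape$protected])
    rows[[paste0("region_", r)]] <-
      row_for("region", r, pa_r, regional_pairs[[r]], up_r, r)
  }
  pa_levels <- sort(unique(landscape$pa_id[!is.na(landscape$pa_id)]))
  ctrl_of <- function(ids) {
    if (is.null(national_pairs) || !nrow(national_pairs)) return(NULL)
    sel <- national_pairs$treated_id %in% ids
    national_pairs[sel, , drop = FALSE]
  }
  for (p in pa_levels) {
    ids <- landscape$cell_id[!is.na(landscape$pa_id) & landscape$pa_id == p]
    rows[[paste0("pa_", p)]] <- row_for("PA", p, ids, ctrl_of(ids),
                                        loss_unprot, NA_character_)
  }
  if ("iucn_cat" %in% names(landscape)) {
    for (cc in sort(unique(stats::na.omit(landscape$iucn_cat)))) {
      ids <- landscape$cell_id[!is.na(landscape$iucn_cat) &
                                 landscape$iucn_cat == cc]
      rows[[paste0("iucn_", cc)]] <- row_for("IUCN", cc, ids, ctrl_of(ids),
                                             loss_unprot, NA_character_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- !is.na(out$loss_pa_pct) & !is.na(out$loss_control_pct)
  out$percent_reduction[ok] <- ifelse(
    out$loss_control_pct[ok] == 0, NA_real_,
    100 * (out$loss_control_pct[ok] - out$loss_pa_pct[ok]) /
      out$loss_control_pct[ok])
  class(out) <- c("effectiveness_report", "data.frame")
  out
}

#' @export
print.effectiveness_report <- function(x, ...) {
  cat("Protected-area effectiveness report\n")
  nat <- x[x$level == "national", , drop = FALSE]
  if (nrow(nat)) {
    cat(sprintf(
      "  national: PA loss %.2f%%, matched controls %.2f%%, reduction %.1f%%\n",
      nat$loss_pa_pct, nat$loss_control_pct, nat$percent_reduction))
  }
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
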