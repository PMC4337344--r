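# Hormone panel I/O, z-standardization, cycle-phase labeling.

hormone_cols <- c("estradiol", "progesterone", "lh", "cortisol")
panel_required_cols <- c("scan_id", "session_id", "cycle_day", hormone_cols)

validate_panel <- function(panel) {
  missing <- setdiff(panel_required_cols, names(panel))
  if (length(missing) > 0)
    stop("hormone panel is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("session_id", "cycle_day", hormone_cols)) {
    if (!is.numeric(panel[[col]]))
      stop("hormone panel column '", col, "' must be numeric")
  }
  if (anyDuplicated(panel$scan_id))
    stop("hormone panel has duplicate scan_id values")
  if (any(panel$cycle_day < 1, na.rm = TRUE))
    stop("hormone panel cycle_day must be >= 1")
  invisible(panel)
}

#' Load a per-scan hormone table
#'
#' Reads a CSV with one row per scan and columns `scan_id`, `session_id`,
#' `cycle_day` (days since menses onset, >= 1), and serum levels `estradiol`,
#' `progesterone`, `lh`, `cortisol`. Missing hormone values are kept and
#' flagged with a warning, never dropped.
#'
#' @param path CSV file path.
#' @return A `data.frame` of class `hormone_panel`.
#' @export
load_hormone_table <- function(path) {
  if (!file.exists(path)) stop("load_hormone_table: file not found: ", path)
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_panel(panel)
  n_na <- sum(is.na(panel[hormone_cols]))
  if (n_na > 0)
    warning("hormone panel contains ", n_na, " missing hormone value(s)")
  class(panel) <- c("hormone_panel", "data.frame")
  panel
}

#' Write a hormone panel to CSV
#'
#' @param panel A `hormone_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hormone_table <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Z-standardize hormone columns
#'
#' Adds (or recomputes) `z_estradiol`, `z_progesterone`, `z_lh`, `z_cortisol`
#' from the raw columns, using the sample (n-1) standard deviation. With
#' `scope = "all_scans"` both scanning sessions are pooled (the convention
#' used when plotting the hormone curves); `"per_session"` standardizes
#' within each session, relevant when sessions are months apart on
#' different assay plates.
#'
#' @param panel A `hormone_panel`.
#' @param scope `"all_scans"` (default) or `"per_session"`.
#' @return The panel with `z_*` columns filled; raw columns untouched.
#' @export
zstandardize <- function(panel, scope = c("all_scans", "per_session")) {
  scope <- match.arg(scope)
  validate_panel(panel)
  groups <- if (scope == "all_scans") rep(1L, nrow(panel)) else panel$session_id
  for (col in hormone_cols) {
    z <- rep(NA_real_, nrow(panel))
    for (g in unique(groups)) {
      idx <- which(groups == g)
      if (length(idx) < 2)
        stop("zstandardize: group ", g, " has fewer than 2 scans")
      x <- panel[[col]][idx]
      s <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(s) || s == 0)
        stop("zstandardize: column '", col, "' has zero variance in group ", g)
      z[idx] <- (x - mean(x, na.rm = TRUE)) / s
    }
    panel[[paste0("z_", col)]] <- z
  }
  class(panel) <- unique(c("hormone_panel", class(panel)))
  panel
}

#' Label menstrual-cycle phase from the LH surge
#'
#' Locates the LH surge as the scan day with maximal LH, required to exceed
#' the panel's LH median by at least two panel standard deviations. Ovulation
#' is taken as the day after the surge. Scans are labeled `follicular`
#' before the surge day minus one, `periovulatory` on the surge day plus or
#' minus one day, and `luteal` from two days after the surge onward. If no
#' surge passes the criterion, all scans stay unlabeled (`NA`) with a
#' warning.
#'
#' @param panel A `hormone_panel` with `cycle_day` and `lh`.
#' @return The panel with a `phase` character column and attributes
#'   `surge_day` and `ovulation_day` (`NA` if undetected).
#' @export
label_phase <- function(panel) {
  validate_panel(panel)
  lh <- panel$lh
  i_max <- which.max(lh)
  surge_ok <- length(unique(lh)) > 1 &&
    lh[i_max] >= stats::median(lh, na.rm = TRUE) +
      2 * stats::sd(lh, na.rm = TRUE)
  if (!surge_ok) {
    warning("label_phase: no LH surge detected; scans left unlabeled")
    panel$phase <- NA_character_
    attr(panel, "surge_day") <- NA_real_
    attr(panel, "ovulation_day") <- NA_real_
    return(panel)
  }
  surge_day <- panel$cycle_day[i_max]
  d <- panel$cycle_day
  panel$phase <- ifelse(d <= surge_day - 2, "follicular",
                 ifelse(d <= surge_day + 1, "periovulatory", "luteal"))
  attr(panel, "surge_day") <- surge_day
  attr(panel, "ovulation_day") <- surge_day + 1
  panel
}
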