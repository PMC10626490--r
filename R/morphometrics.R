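#' Internode surface area from the two-truncated-cone model
#'
#' Models a stem internode as the lateral walls of two intersecting
#' truncated cones meeting at the internode midpoint (which typically has
#' the smallest diameter):
#' `SA = (h/2) (D_top + D_mid) (pi/2) + (h/2) (D_mid + D_base) (pi/2)`,
#' with the slant height of each cone approximated by half the internode
#' length. With all diameters equal this reduces to the cylinder lateral
#' area `pi * d * h`.
#'
#' @param length_cm Internode length h (cm).
#' @param d_top,d_mid,d_base Diameters at the top (below the nodal plexus),
#'   midpoint, and base (above the pulvinus), in cm. Vectors are recycled
#'   elementwise.
#' @return Surface area(s) in cm^2.
#' @export
internode_surface_area <- function(length_cm, d_top, d_mid, d_base) {
  vals <- cbind(length_cm, d_top, d_mid, d_base)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all internode measurements must be positive")
  (length_cm / 2) * (d_top + d_mid) * (pi / 2) +
    (length_cm / 2) * (d_mid + d_base) * (pi / 2)
}

#' Cuticular wax load per unit surface area
#'
#' Sums the masses of the sequential solvent washes of one organ and divides
#' by its surface area.
#'
#' @param wash_masses_ug Numeric vector of per-wash wax masses (micrograms);
#'   the standard protocol uses three hexane washes.
#' @param surface_area_cm2 Organ surface area (cm^2), positive.
#' @return Wax load in micrograms per cm^2.
#' @export
wax_load <- function(wash_masses_ug, surface_area_cm2) {
  if (length(surface_area_cm2) != 1 || !is.finite(surface_area_cm2) ||
      surface_area_cm2 <= 0)
    stop("surface area must be a single positive number")
  if (any(wash_masses_ug < 0)) stop("wash masses must be nonnegative")
  sum(wash_masses_ug) / surface_area_cm2
}

#' Wax-class composition as percent of total ion current
#'
#' Per sample, each component class's share is 100 times its summed peak
#' area over the total peak area of the sample (background subtraction is
#' assumed to have happened upstream, in peak integration). Per group, means
#' and standard deviations across samples are reported.
#'
#' @param peaks Data frame with columns `sample`, `group`, `class`, `area`
#'   (peak areas >= 0, classes from e.g. alcohol / aldehyde / alkane /
#'   ester / other).
#' @return List with `percent` (data frame `sample`, `group`, `class`,
#'   `percent`; class percentages sum to 100 per sample) and `group_stats`
#'   (data frame `group`, `class`, `mean`, `sd`, `n`).
#' @export
composition_percent_tic <- function(peaks) {
  req <- c("sample", "group", "class", "area")
  if (!all(req %in% names(peaks)))
    stop("'peaks' needs columns: ", paste(req, collapse = ", "))
  if (any(peaks$area < 0)) stop("peak areas must be nonnegative")
  tot <- tapply(peaks$area, peaks$sample, sum)
  if (any(tot == 0))
    stop("zero total peak area in sample(s): ",
         paste(names(tot)[tot == 0], collapse = ", "))
  cls <- sort(unique(peaks$class))
  samp <- unique(peaks[, c("sample", "group")])
  grid <- expand.grid(sample = samp$sample, class = cls,
                      stringsAsFactors = FALSE)
  grid$group <- samp$group[match(grid$sample, samp$sample)]
  area <- tapply(peaks$area, list(peaks$sample, peaks$class), sum,
                 default = 0)
  grid$percent <- 100 * area[cbind(grid$sample, grid$class)] /
    as.numeric(tot[grid$sample])
  grid <- grid[order(grid$sample, grid$class), c("sample", "group", "class", "percent")]
  rownames(grid) <- NULL
  gs <- do.call(rbind, lapply(split(grid, list(grid$group, grid$class), drop = TRUE),
    function(d) data.frame(group = d$group[1], class = d$class[1],
                           mean = mean(d$percent),
                           sd = if (nrow(d) > 1) sd(d$percent) else NA_real_,
                           n = nrow(d), stringsAsFactors = FALSE)))
  gs <- gs[order(gs$group, gs$class), ]
  rownames(gs) <- NULL
  list(percent = grid, group_stats = gs)
}

#' Group comparisons of wax-class percentages
#'
#' Per class and non-reference group, a two-sided Welch t-test of the
#' per-sample percentages against the reference group, with significance
#' stars at p < 0.01 (`*`) and p < 0.001 (`**`).
#'
#' @param percent The `percent` data frame from [composition_percent_tic()]
#'   (columns `sample`, `group`, `class`, `percent`).
#' @param reference Reference group label (default `"P1-7"`, the youngest
#'   phytomer group).
#' @return Data frame with columns `group`, `class`, `mean`,
#'   `mean_reference`, `p`, `stars`.
#' @export
composition_group_test <- function(percent, reference = "P1-7") {
  if (!reference %in% percent$group)
    stop("reference group '", reference, "' not present")
  cls <- sort(unique(percent$class))
  others <- setdiff(sort(unique(percent$group)), reference)
  rows <- list()
  for (g in others) for (k in cls) {
    x <- percent$percent[percent$group == g & percent$class == k]
    y <- percent$percent[percent$group == reference & percent$class == k]
    if (length(x) < 2 || length(y) < 2)
      stop("group with <2 samples for class ", k)
    p <- if (sd(x) == 0 && sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    } else t.test(x, y)$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, class = k, mean = mean(x), mean_reference = mean(y),
      p = p, stars = if (p < 0.001) "**" else if (p < 0.01) "*" else "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Surface area and wax load for a measurement table
#'
#' Convenience wrapper applying [internode_surface_area()] and [wax_load()]
#' row-wise to a morphometric measurement table.
#'
#' @param measurements Data frame with columns `phytomer`, `length_cm`,
#'   `d_top_cm`, `d_mid_cm`, `d_base_cm`, and optionally wash-mass columns
#'   `wash1_ug`, `wash2_ug`, `wash3_ug` (any number of `wash*_ug` columns).
#' @return The table with added `surface_area_cm2` and, when wash columns
#'   are present, `wax_total_ug` and `wax_load_ug_cm2`.
#' @export
morphometrics_table <- function(measurements) {
  req <- c("phytomer", "length_cm", "d_top_cm", "d_mid_cm", "d_base_cm")
  if (!all(req %in% names(measurements)))
    stop("'measurements' needs columns: ", paste(req, collapse = ", "))
  out <- measurements
  out$surface_area_cm2 <- internode_surface_area(
    out$length_cm, out$d_top_cm, out$d_mid_cm, out$d_base_cm)
  wash_cols <- grep("^wash[0-9]+_ug$", names(out), value = TRUE)
  if (length(wash_cols)) {
    out$wax_total_ug <- rowSums(out[, wash_cols, drop = FALSE])
    out$wax_load_ug_cm2 <- out$wax_total_ug / out$surface_area_cm2
  }
  out
}
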