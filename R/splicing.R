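# dmpi8 splicing efficiency from gel band intensities.
#
# efficiency  = spliced / (spliced + unspliced)       (CBP20 cancels)
# total_dper  = (spliced + unspliced) / cbp20         (CBP20-normalized)

#' Splicing efficiency and total transcript level from band intensities
#'
#' Vectorized over points. The efficiency is the proportion of transcripts
#' with the intron removed and is invariant to rescaling all three intensities
#' by any positive constant; the total level is normalized to the CBP20
#' loading control.
#'
#' @param spliced,unspliced,cbp20 non-negative band intensities (arbitrary
#'   units); `spliced + unspliced` and `cbp20` must be positive.
#' @return data.frame with `efficiency` (in `[0, 1]`) and `total_dper`.
#' @export
splicing_efficiency <- function(spliced, unspliced, cbp20) {
  if (any(spliced < 0) || any(unspliced < 0) || any(cbp20 < 0))
    stop("intensities must be non-negative")
  tot <- spliced + unspliced
  if (any(tot == 0)) stop("spliced + unspliced = 0: efficiency undefined")
  if (any(cbp20 == 0)) stop("cbp20 = 0: normalization undefined")
  data.frame(efficiency = spliced / tot, total_dper = tot / cbp20)
}

#' Daily splicing curve per group
#'
#' Pools per-line efficiencies into a per-ZT group mean, with lines as the
#' replication unit. All lines of a group must share the same ZT grid.
#'
#' @param points data.frame with columns `line`, `group`, `zt`, and either
#'   `efficiency` or the three intensity columns (`spliced`, `unspliced`,
#'   `cbp20`), from which efficiency is derived.
#' @return data.frame per (group, zt): `mean_efficiency`, `sd`, `n_lines`.
#' @export
daily_curve <- function(points) {
  if (!"efficiency" %in% names(points))
    points$efficiency <- splicing_efficiency(points$spliced, points$unspliced,
                                             points$cbp20)$efficiency
  stopifnot(all(c("line", "group", "zt") %in% names(points)))
  for (g in unique(points$group)) {
    zt_by_line <- tapply(points$zt[points$group == g],
                         points$line[points$group == g],
                         function(z) paste(sort(z), collapse = ","))
    if (length(unique(zt_by_line)) != 1)
      stop("mismatched ZT grids within group '", g, "'")
  }
  agg <- stats::aggregate(efficiency ~ group + zt, points,
                          function(e) c(m = mean(e), s = stats::sd(e),
                                        n = length(e)))
  out <- data.frame(group = agg$group, zt = agg$zt,
                    mean_efficiency = agg$efficiency[, "m"],
                    sd = agg$efficiency[, "s"],
                    n_lines = as.integer(agg$efficiency[, "n"]))
  out[order(out$group, out$zt), ]
}

#' Compare two groups' daily splicing curves
#'
#' One-way ANOVA with group as the factor, on per-line per-timepoint
#' efficiencies (the line mean at each ZT is the observational unit).
#'
#' @param points as in [daily_curve()], containing exactly the two groups (or
#'   use `groups` to select them).
#' @param groups optional pair of group labels to compare.
#' @return a `test_result` (see [anova_oneway()]).
#' @export
compare_curves <- function(points, groups = NULL) {
  if (!"efficiency" %in% names(points))
    points$efficiency <- splicing_efficiency(points$spliced, points$unspliced,
                                             points$cbp20)$efficiency
  if (!is.null(groups)) points <- points[points$group %in% groups, ]
  gs <- unique(points$group)
  if (length(gs) < 2) stop("need two groups to compare")
  nlines <- tapply(points$line, points$group, function(x) length(unique(x)))
  if (any(nlines < 2)) stop("need at least 2 lines per group")
  anova_oneway(points$efficiency, points$group)
}
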