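#' Specification of a two-group longitudinal organoid cohort
#'
#' Emulates a control vs disease-model study design: organoids imaged
#' weekly, with a mid-study switch to neuronal differentiation medium after
#' which the two groups diverge.  Group trends are expressed as weekly
#' retention/growth rates applied to the phantom generator's ground-truth
#' parameters: directional-cell density and surface-rosette count decay by
#' their retention rates post-switch, while the lipid-droplet area fraction
#' grows by its growth rate.  Before the switch both groups follow the same
#' shared dynamics, so pre-switch contrasts are null by construction.
#'
#' @param n_control,n_experimental organoids per group.
#' @param weeks ordered integer time labels.
#' @param switch_week week of the differentiation-medium switch; must be a
#'   member of `weeks`.
#' @param control,experimental named lists with elements
#'   `directional_retention`, `droplet_growth`, `rosette_retention`
#'   (per-week multiplicative rates, all >= 0) applied after the switch.
#' @param pre_droplet_growth shared pre-switch weekly droplet growth rate.
#' @param base_phantom a [phantom_spec()] giving week-one ground truth for
#'   every organoid; per-organoid seeds are derived from `seed`.
#' @param seed integer master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 6, n_experimental = 6,
                        weeks = 1:4, switch_week = 2,
                        control = list(directional_retention = 0.5,
                                       droplet_growth = 1.2,
                                       rosette_retention = 0.6),
                        experimental = list(directional_retention = 1.0,
                                            droplet_growth = 1.5,
                                            rosette_retention = 1.0),
                        pre_droplet_growth = 1.1,
                        base_phantom = phantom_spec(image_size = 192,
                                                    pixel_size = 2,
                                                    organoid_axes = c(150, 120),
                                                    rosette_count = 8,
                                                    rosette_radius_range = c(14, 22),
                                                    droplet_area_fraction = 0.02),
                        seed = 1L) {
  if (!switch_week %in% weeks) stopf("switch_week must be a member of weeks")
  for (g in list(control, experimental))
    if (any(unlist(g) < 0)) stopf("retention/growth rates must be >= 0")
  structure(list(n_control = as.integer(n_control),
                 n_experimental = as.integer(n_experimental),
                 weeks = weeks, switch_week = switch_week,
                 control = control, experimental = experimental,
                 pre_droplet_growth = pre_droplet_growth,
                 base_phantom = base_phantom, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Ground-truth parameters for one group at one week.
cohort_week_truth <- function(cspec, group, week) {
  g <- if (group == "control") cspec$control else cspec$experimental
  base <- cspec$base_phantom
  k_post <- max(0, week - cspec$switch_week)
  k_pre <- min(week, cspec$switch_week) - cspec$weeks[1]
  list(directional_cell_density =
         base$directional_cell_density * g$directional_retention^k_post,
       droplet_area_fraction =
         min(0.3, base$droplet_area_fraction *
               cspec$pre_droplet_growth^k_pre * g$droplet_growth^k_post),
       rosette_count = max(0L, as.integer(round(
         base$rosette_count * g$rosette_retention^k_post))))
}

#' Generate a two-group longitudinal cohort of phantoms
#'
#' @param cspec a [cohort_spec()].
#' @param quiet suppress per-phantom progress.
#' @return object of class `organoid_cohort`: a list with `phantoms` (list of
#'   `organoid_phantom`), `metadata` (data.frame with organoid, group, week,
#'   and the ground-truth parameters used), and `spec`.
#' @export
generate_two_group_cohort <- function(cspec, quiet = TRUE) {
  stopifnot(inherits(cspec, "cohort_spec"))
  phantoms <- list()
  meta <- NULL
  idx <- 0L
  for (group in c("control", "experimental")) {
    ng <- if (group == "control") cspec$n_control else cspec$n_experimental
    for (i in seq_len(ng)) {
      oid <- paste0(if (group == "control") "C" else "E", i)
      for (week in cspec$weeks) {
        idx <- idx + 1L
        tr <- cohort_week_truth(cspec, group, week)
        ps <- cspec$base_phantom
        ps$directional_cell_density <- tr$directional_cell_density
        ps$droplet_area_fraction <- tr$droplet_area_fraction
        ps$rosette_count <- tr$rosette_count
        ps$seed <- as.integer((cspec$seed + 7919 * idx) %% 2147483647)
        phantoms[[idx]] <- generate_organoid_phantom(ps)
        meta <- rbind(meta, data.frame(
          organoid = oid, group = group, week = week,
          gt_directional_density = tr$directional_cell_density,
          gt_droplet_fraction = tr$droplet_area_fraction,
          gt_rosette_count = tr$rosette_count,
          realized_droplet_fraction = phantoms[[idx]]$droplet_fraction,
          stringsAsFactors = FALSE))
        if (!quiet) message(sprintf("phantom %d: %s week %s", idx, oid, week))
      }
    }
  }
  structure(list(phantoms = phantoms, metadata = meta, spec = cspec),
            class = "organoid_cohort")
}

#' @export
print.organoid_cohort <- function(x, ...) {
  cat(sprintf("organoid cohort: %d phantoms (%d control + %d experimental organoids, weeks %s)\n",
              length(x$phantoms), x$spec$n_control, x$spec$n_experimental,
              paste(range(x$spec$weeks), collapse = "-")))
  invisible(x)
}
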