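#' Run the systematic shortening experiment on a cohort
#'
#' For each bone: the reference frame (CS100) is placed automatically on the
#' full mesh; the bone is then clipped to each retained length along the
#' reference z-axis (always from the full mesh, so "percentage of radial
#' length" refers to one consistent length), the frame is re-placed
#' automatically, and the pose error versus CS100 is recorded. A subset of
#' bones additionally receives simulated manual placements (observers x
#' replicates per length), perturbations of the generator's ground truth
#' evaluated against the same CS100 reference. Placement failures are
#' recorded per row with `failed = TRUE`, never dropped silently. Fully
#' deterministic given `seed`.
#'
#' @param cohort list from [generate_cohort()].
#' @param lengths retained-length percentages, subset of 10, 20, ..., 100.
#' @param manual_noise a [manual_noise_model()], or `NULL` to skip manual
#'   simulation.
#' @param seed master seed for the manual simulator.
#' @param manual_bones number of bones receiving manual placements (drawn
#'   deterministically from the cohort; default 5).
#' @param n_observers,n_replicates manual design (defaults 3 observers, 10
#'   replicates: 150 sets per length for 5 bones).
#' @param global_up distal direction hint passed to [place_rcs()].
#' @return data.frame with one row per (bone, length, method, observer,
#'   replicate): columns bone_id, length_pct, method, observer_id, replicate,
#'   dx, dy, dz, phiy, phix, phiz, d_err, phi_err, failed, gender_label,
#'   age_years, growth_plate_flag.
#' @export
run_experiment <- function(cohort, lengths = seq(10L, 100L, 10L),
                           manual_noise = manual_noise_model(), seed = 1L,
                           manual_bones = 5L, n_observers = 3L,
                           n_replicates = 10L, global_up = c(0, 0, 1)) {
  if (!is.list(cohort) || length(cohort) == 0L) {
    abort_radcs("cohort must be a non-empty list", "radcs_validation_error")
  }
  lengths <- as.integer(lengths)
  if (!all(lengths %in% seq(10L, 100L, 10L))) {
    abort_radcs("lengths must be a subset of 10, 20, ..., 100",
                "radcs_validation_error")
  }
  do_manual <- !is.null(manual_noise) && manual_bones > 0L
  manual_set <- if (do_manual) {
    with_seed(seed, sort(sample(length(cohort),
                                min(manual_bones, length(cohort)))))
  } else {
    integer(0)
  }
  seed_pool <- derive_seeds(seed + 1L,
                            max(1L, length(manual_set) * length(lengths) *
                                  n_observers * n_replicates))
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    seed_pool[seed_i]
  }

  rows <- list()
  na_err <- as.data.frame(structure(
    list(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
         NA_real_, NA_real_),
    names = c("dx", "dy", "dz", "phiy", "phix", "phiz", "d_err", "phi_err")))
  add_row <- function(bone, length_pct, method, observer_id, replicate,
                      err_df, failed) {
    cov <- bone$covariates
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(bone_id = bone$bone_id, length_pct = length_pct,
                 method = method, observer_id = observer_id,
                 replicate = replicate),
      err_df,
      data.frame(failed = failed,
                 gender_label = cov$gender_label,
                 age_years = cov$age_years,
                 growth_plate_flag = cov$growth_plate_flag))
  }

  for (bi in seq_along(cohort)) {
    bone <- cohort[[bi]]
    ref <- tryCatch(place_rcs(bone$mesh, global_up = global_up)$cs,
                    radcs_error = function(e) NULL)
    if (is.null(ref)) {
      for (l in lengths) {
        add_row(bone, l, "auto", NA_character_, 1L, na_err, TRUE)
      }
      next
    }
    for (l in lengths) {
      err <- tryCatch({
        clipped <- clip_fraction(bone$mesh, ref$z_axis, l / 100)
        cs <- place_rcs(clipped, global_up = global_up)$cs
        as.data.frame(pose_error(ref, cs))
      }, radcs_error = function(e) NULL)
      add_row(bone, l, "auto", NA_character_, 1L,
              if (is.null(err)) na_err else err, is.null(err))
    }
    if (bi %in% manual_set) {
      for (l in lengths) {
        for (o in seq_len(n_observers)) {
          for (r in seq_len(n_replicates)) {
            cs <- simulate_manual_placement(bone$truth, l, manual_noise,
                                            seed = next_seed())
            add_row(bone, l, "manual_sim", sprintf("obs%d", o), r,
                    as.data.frame(pose_error(ref, cs)), FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-length accuracy/precision summary of an experiment table
#'
#' Medians and interquartile ranges of the absolute errors per length and
#' method (accuracy is summarized on absolute values; signed components stay
#' in the raw table).
#'
#' @param records data.frame from [run_experiment()].
#' @param metric column to summarize (default `"phi_err"`).
#' @return data.frame with length_pct, method, n, median, q1, q3, min, max.
#' @export
summarize_experiment <- function(records, metric = "phi_err") {
  if (!metric %in% names(records)) {
    abort_radcs(sprintf("no column '%s' in records", metric),
                "radcs_validation_error")
  }
  d <- records[!records$failed & is.finite(records[[metric]]), , drop = FALSE]
  grp <- split(d, list(d$length_pct, d$method), drop = TRUE)
  out <- lapply(grp, function(g) {
    s <- summarize_errors(abs(g[[metric]]))
    data.frame(length_pct = g$length_pct[1L], method = g$method[1L],
               n = nrow(g), median = s$median, q1 = s$q1, q3 = s$q3,
               min = s$min, max = s$max)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$method, out$length_pct), ]
  rownames(out) <- NULL
  out
}
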