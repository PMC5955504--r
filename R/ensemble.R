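#' Ensemble fusion configuration
#'
#' @param vote_threshold Fraction of members, in (0, 1\], that must vote a
#'   pixel positive; the published operating point is 0.5. A mean vote
#'   exactly equal to the threshold counts as positive (inclusive `>=`), so
#'   a 5-of-10 tie at threshold 0.5 is positive.
#' @param member_binarize_threshold Probability cutoff, in (0, 1\], applied
#'   to each member map before averaging (equally weighted binary pixels).
#' @param n_members Number of ensemble members (default 10).
#' @param average_probabilities If `TRUE`, average raw member probabilities
#'   instead of binarised votes (not the published method; off by default).
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(vote_threshold = 0.5,
                            member_binarize_threshold = 0.5,
                            n_members = 10,
                            average_probabilities = FALSE) {
  if (vote_threshold <= 0 || vote_threshold > 1) {
    abort("`vote_threshold` must lie in (0, 1]")
  }
  if (member_binarize_threshold <= 0 || member_binarize_threshold > 1) {
    abort("`member_binarize_threshold` must lie in (0, 1]")
  }
  structure(list(vote_threshold = vote_threshold,
                 member_binarize_threshold = member_binarize_threshold,
                 n_members = as.integer(n_members),
                 average_probabilities = isTRUE(average_probabilities)),
            class = "ensemble_config")
}

#' Patient-grouped fold assignment
#'
#' Assigns every patient to exactly one of `n_folds` folds (so all images
#' of a patient share a fold), with fold sizes differing by at most one
#' patient; the assignment order is a seeded shuffle.
#'
#' @param patient_ids Character vector (duplicates allowed; folds are
#'   assigned to unique patients).
#' @param n_folds Number of folds (default 10); must not exceed the number
#'   of distinct patients.
#' @param rng_seed Integer seed.
#' @return A tibble (`fold_plan`) with columns `patient_id`, `fold`.
#' @export
make_folds <- function(patient_ids, n_folds = 10, rng_seed = 1L) {
  ids <- unique(as.character(patient_ids))
  if (n_folds > length(ids)) {
    abort(sprintf("cannot make %d folds from %d patients", n_folds, length(ids)))
  }
  withr::with_seed(rng_seed, {
    shuffled <- sample(ids)
    fold <- rep(seq_len(n_folds), length.out = length(shuffled))
    structure(tibble::tibble(patient_id = shuffled, fold = as.integer(fold)) |>
                dplyr::arrange(.data$patient_id),
              class = c("fold_plan", class(tibble::tibble())),
              n_folds = as.integer(n_folds), rng_seed = as.integer(rng_seed))
  })
}

#' Train the ten-fold U-net ensemble
#'
#' Member `k` trains on all folds except `k` and validates on fold `k`
#' (the 9:1 grouped split), with an independent random initialisation
#' derived from `rng_seed`. Returns all members with their validation Dice.
#'
#' @param dataset Dataset tibble from [generate_dataset()].
#' @param fold_plan A [make_folds()] plan covering the dataset's patients.
#' @param net_config A [network_config()] (typically [scale_profile()]).
#' @param rng_seed Master seed for member initialisations.
#' @param verbose Print per-member progress.
#' @return An object of class `unet_ensemble`: list of trained members,
#'   the fold plan, configs and a `val_dice` tibble.
#' @export
train_ensemble <- function(dataset, fold_plan, net_config = scale_profile(),
                           rng_seed = 1L, verbose = FALSE) {
  missing_pat <- setdiff(unique(dataset$patient_id), fold_plan$patient_id)
  if (length(missing_pat) > 0) {
    abort(sprintf("fold plan does not cover patients: %s",
                  paste(head(missing_pat, 3), collapse = ", ")))
  }
  folds <- sort(unique(fold_plan$fold))
  ds <- dplyr::left_join(dataset, fold_plan, by = "patient_id")
  members <- vector("list", length(folds))
  for (k in folds) {
    tr <- ds[ds$fold != k, ]
    va <- ds[ds$fold == k, ]
    if (nrow(tr) == 0) abort(sprintf("fold %d leaves an empty training set", k))
    cfg <- net_config
    cfg$rng_seed <- derive_seed(rng_seed, k)
    model <- build_network(cfg)
    model <- train_member(model, tr, va)
    model$fold <- k
    members[[k]] <- model
    if (verbose) {
      inform(sprintf("member %d/%d: validation Dice %.3f (epoch %d)",
                     k, length(folds), model$val_dice,
                     max(model$history$epoch)))
    }
  }
  structure(list(members = members, fold_plan = fold_plan,
                 net_config = net_config, rng_seed = as.integer(rng_seed),
                 val_dice = tibble::tibble(
                   fold = folds,
                   val_dice = vapply(members, function(m) m$val_dice, numeric(1)))),
            class = "unet_ensemble")
}

#' @export
print.unet_ensemble <- function(x, ...) {
  cat(sprintf("<unet_ensemble> %d members, validation Dice %.3f +- %.3f\n",
              length(x$members), mean(x$val_dice$val_dice),
              sd(x$val_dice$val_dice)))
  invisible(x)
}

#' Per-pixel majority-vote fusion
#'
#' Each member probability map is binarised at
#' `member_binarize_threshold`; the binary maps are averaged with equal
#' weights and a pixel is declared lesion when the average reaches
#' `vote_threshold` (inclusive `>=`, so the 5-of-10 tie at the default
#' threshold is positive). Fusing in any member order yields the identical
#' mask.
#'
#' @param maps List of [probability_map()]s (or matrices) on one grid.
#' @param config An [ensemble_config()].
#' @return A [segmentation_mask()] with role `"prediction"`.
#' @export
majority_vote <- function(maps, config = ensemble_config()) {
  if (length(maps) == 0) abort("`maps` must be nonempty")
  rasters <- lapply(maps, as_raster)
  d0 <- dim(rasters[[1]])
  if (!all(vapply(rasters, function(m) all(dim(m) == d0), logical(1)))) {
    abort("all probability maps must share one grid")
  }
  acc <- matrix(0, d0[1], d0[2])
  for (m in rasters) {
    acc <- acc + if (config$average_probabilities) m else (m >= config$member_binarize_threshold)
  }
  avg <- acc / length(rasters)
  segmentation_mask((avg >= config$vote_threshold) * 1L, role = "prediction")
}

#' Predict member maps and the fused mask for one image
#'
#' @param ensemble A [train_ensemble()] result.
#' @param image A [bmode_image()] or matrix (original coordinates).
#' @param config An [ensemble_config()].
#' @return List with `maps` (member probability maps), `mask` (fused
#'   prediction mapped back to the original grid), `mask_net` (fused mask
#'   on the network grid), `vote_fraction` (mean binary vote raster) and
#'   the `placement` record.
#' @export
predict_ensemble <- function(ensemble, image, config = ensemble_config()) {
  input_size <- ensemble$net_config$input_size
  pr <- preprocess_record(image, mask = NULL, input_size)
  maps <- purrr::imap(ensemble$members, function(m, k) {
    predict_map(m, pr$x, model_id = sprintf("fold%02d", k))
  })
  fused <- majority_vote(maps, config)
  votes <- Reduce(`+`, lapply(maps, function(m) {
    (m$pixels >= config$member_binarize_threshold) * 1
  })) / length(maps)
  back <- map_back(fused$pixels, pr$placement)
  list(maps = maps, mask = segmentation_mask(back, role = "prediction"),
       mask_net = fused, vote_fraction = votes, placement = pr$placement)
}

#' Mean-Dice curve over majority-voting thresholds
#'
#' Re-fuses stored member maps at each threshold and reports the mean Dice
#' over the evaluation set. Raising the threshold can only shrink the
#' predicted-positive set of every image (vote masks are nested), which the
#' returned per-image areas make checkable.
#'
#' @param maps_per_image List (one element per image) of lists of member
#'   probability maps.
#' @param truths List of ground-truth masks on the same grid.
#' @param thresholds Numeric vector of at least two thresholds in (0, 1\].
#' @param config Base [ensemble_config()] (binarisation threshold reused).
#' @return A tibble with `threshold`, `mean_dice`, `mean_area`.
#' @export
vote_threshold_sweep <- function(maps_per_image, truths,
                                 thresholds = seq(0.1, 1, by = 0.1),
                                 config = ensemble_config()) {
  if (length(maps_per_image) == 0) abort("empty evaluation set")
  if (length(thresholds) < 2) abort("need at least two thresholds")
  rows <- purrr::map(thresholds, function(t) {
    cfg <- config
    cfg$vote_threshold <- t
    res <- purrr::map2(maps_per_image, truths, function(maps, tr) {
      mk <- majority_vote(maps, cfg)
      c(dice = dice_coef(mk, tr), area = sum(mk$pixels))
    })
    tibble::tibble(threshold = t,
                   mean_dice = mean(vapply(res, `[[`, numeric(1), "dice")),
                   mean_area = mean(vapply(res, `[[`, numeric(1), "area")))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("vote_sweep", class(out))
  out
}

#' Mean Dice as a function of ensemble size
#'
#' Fuses the first `m` members (deterministic fold order) for each count
#' in `counts`, optionally averaging over seeded random member subsets,
#' and reports the mean Dice over the evaluation set.
#'
#' @inheritParams vote_threshold_sweep
#' @param counts Integer ensemble sizes to evaluate.
#' @param n_subsets Number of random member subsets to average per count
#'   (1 = deterministic prefix order).
#' @param rng_seed Seed for subset draws.
#' @return A tibble with `n_members`, `mean_dice`, `sd_dice`.
#' @export
member_count_sweep <- function(maps_per_image, truths, counts,
                               config = ensemble_config(),
                               n_subsets = 1, rng_seed = 1L) {
  n_avail <- length(maps_per_image[[1]])
  if (any(counts > n_avail)) {
    abort(sprintf("requested up to %d members but only %d are available",
                  max(counts), n_avail))
  }
  eval_subset <- function(sel) {
    mean(purrr::map2_dbl(maps_per_image, truths, function(maps, tr) {
      dice_coef(majority_vote(maps[sel], config), tr)
    }))
  }
  withr::with_seed(rng_seed, {
    rows <- purrr::map(counts, function(m) {
      vals <- if (n_subsets <= 1) {
        eval_subset(seq_len(m))
      } else {
        vapply(seq_len(n_subsets), function(i) eval_subset(sample(n_avail, m)),
               numeric(1))
      }
      tibble::tibble(n_members = m, mean_dice = mean(vals),
                     sd_dice = if (length(vals) > 1) sd(vals) else 0)
    })
    out <- dplyr::bind_rows(rows)
    class(out) <- c("member_sweep", class(out))
    out
  })
}
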