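# Shared fixtures, built lazily and cached for the session so expensive
# objects (the trained desk-scale ensemble) are constructed once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small deterministic mask pair on an arbitrary grid.
random_mask <- function(h, w, p = 0.3) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

# The study-condition phantom cohort: 50 patients x 2 views (100 images,
# 64 px) for training, 10 patients x 2 for held-out testing.
acceptance_cohort <- function() {
  fixture("cohort", function() {
    list(train = generate_dataset(50, 2, rng_seed = 1234),
         test = {
           ds <- generate_dataset(10, 2, rng_seed = 424243)
           ds$patient_id <- sub("^P", "T", ds$patient_id)
           ds$image_id <- sub("^P", "T", ds$image_id)
           ds
         })
  })
}

# Ten-member desk-scale ensemble trained on the acceptance cohort; cached
# because several acceptance properties interrogate it.
acceptance_ensemble <- function() {
  fixture("ensemble", function() {
    cohort <- acceptance_cohort()
    plan <- make_folds(cohort$train$patient_id, n_folds = 10, rng_seed = 7)
    train_ensemble(cohort$train, plan, scale_profile(), rng_seed = 11)
  })
}

# Member probability maps over the held-out cohort, plus matching truths.
acceptance_maps <- function() {
  fixture("maps", function() {
    ens <- acceptance_ensemble()
    cohort <- acceptance_cohort()
    input_size <- ens$net_config$input_size
    prep <- purrr::pmap(cohort$test, function(image, mask, ...) {
      busseg:::preprocess_record(image, mask, input_size)
    })
    list(
      maps = purrr::map(prep, function(p) {
        purrr::imap(ens$members, function(m, k) {
          predict_map(m, p$x, model_id = sprintf("fold%02d", k))
        })
      }),
      truths = purrr::map(prep, "mask"),
      prep = prep
    )
  })
}
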