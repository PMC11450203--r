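# Shared fixtures. Heavy objects are built once per test run and cached in
# this environment so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# small configuration for fast model-level tests
tiny_cfg <- function(seed = 7L, ...) {
  sim_config(n_drugs = 12, n_cell_lines = 8, n_landmark_genes = 40,
             n_fp_bits = 32, doses_per_drug = 4, n_target_classes = 4,
             module_size = 5, n_cells = 150, n_genes = 400,
             seed = seed, ...)
}

# narrow hyperparameter grid so unit-test fits stay fast
tiny_grid <- function() {
  list(nrounds = 50L, max_depth = 4L, eta = 0.3, min_child_weight = 5,
       colsample_bytree = 0.8, subsample = 1)
}

tiny_training_table <- function() {
  fixture("tiny_tab", function() {
    ref <- simulate_reference(tiny_cfg())
    build_training_table(ref$perturbations, ref$curves, ref$fingerprints)
  })
}

tiny_reference <- function() {
  fixture("tiny_ref", function() simulate_reference(tiny_cfg()))
}

tiny_model <- function() {
  fixture("tiny_model", function() {
    fit_inhibition_model(tiny_training_table(),
                         cv = list(repeats = 2L, folds = 5L),
                         n_search = 2L, grid = tiny_grid(), seed = 1L)
  })
}

# constant-target table derived from the tiny table
constant_table <- function(value = 50) {
  tab <- tiny_training_table()
  tab$inhibition_pct <- value
  tab
}
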