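# Shared fixtures, built in code. The cache environment keeps expensive
# artifacts (trained models for the synthetic benchmark) shared across
# test files within one run.
.fixture_cache <- new.env(parent = emptyenv())

# a small complete cohort with deterministic values
tinyCohort <- function(n_per_group = 6, T = 4, seed = 42, p_miss = 0,
                       p_drop = 0) {
  cfg <- defaultSimulationConfig(n_subjects = n_per_group, T = T,
                                 p_miss = p_miss, p_drop = p_drop)
  sim <- simulateCohort(cfg, seed = seed)
  if (p_miss > 0 || p_drop > 0)
    applyMissingness(sim$cohort, p_miss, p_drop, seed = seed + 1)
  else sim$cohort
}

# hand-built 2-subject cohort for file-format tests
handCohortCSV <- function(path, blank_kmmse_at_visit2 = FALSE,
                          blank_edu_after_baseline = FALSE) {
  schema <- defaultFeatureSchema()
  set.seed(7)
  rows <- list()
  for (s in c("A01", "A02")) for (t in 0:2) {
    vals <- setNames(as.list(round(runif(length(schema@names), 1, 3), 3)),
                     schema@names)
    vals$age <- 70 + t; vals$education <- 12; vals$gender <- 1
    vals$apoe4 <- 0
    if (blank_kmmse_at_visit2 && t == 1) vals$kmmse <- NA
    if (blank_edu_after_baseline && t > 0) vals$education <- NA
    rows[[length(rows) + 1]] <-
      data.frame(subject_id = s, visit_year = t,
                 label = if (s == "A01") "abeta_neg" else "abeta_pos",
                 as.data.frame(vals))
  }
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, na = "")
  df
}

# tiny trained model shared across files (seconds to fit)
tinyModel <- function() {
  if (!is.null(.fixture_cache$tiny_model)) return(.fixture_cache$tiny_model)
  sim <- simulateObservedCohort(
    defaultSimulationConfig(n_subjects = 20, T = 4, p_miss = 0.15), seed = 3)
  labels <- abetaGroup(sim$observed)
  sp <- stratifiedSplit(labels, seed = 5)
  ids <- colnames(sim$observed)
  cfg <- defaultTrainConfig(max_epochs = 40, patience = 10,
                            hidden_units = 16, batch_size = 16, seed = 3)
  model <- trainModel(sim$observed, ids[sp$train], ids[sp$val], cfg)
  .fixture_cache$tiny_model <- list(model = model, sim = sim, split = sp,
                                    ids = ids)
  .fixture_cache$tiny_model
}

# The standard synthetic benchmark: 200 subjects/group, T = 4, 20%
# intermittent missingness, seeds 1..5; full model and mean-imputation GRU
# baseline trained per seed. Computed lazily, shared across acceptance
# blocks.
benchmarkRuns <- function(seeds = 1:5) {
  key <- paste0("bench_", paste(seeds, collapse = "_"))
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  runs <- lapply(seeds, function(seed) {
    cfg <- defaultSimulationConfig(n_subjects = 200, T = 4, p_miss = 0.2,
                                   p_drop = 0)
    sim <- simulateObservedCohort(cfg, seed = seed)
    labels <- abetaGroup(sim$observed)
    sp <- stratifiedSplit(labels, seed = stageSeed(seed, "bench"))
    ids <- colnames(sim$observed)
    tcfg <- defaultTrainConfig(max_epochs = 300, patience = 25,
                               hidden_units = 48, batch_size = 64,
                               seed = seed)
    full <- trainModel(sim$observed, ids[sp$train], ids[sp$val], tcfg)
    grum <- gruMBaseline(sim$observed, ids[sp$train], ids[sp$val], tcfg)
    list(seed = seed, sim = sim, split = sp, ids = ids,
         full = full, grum = grum,
         metrics_full = regressionMetrics(full, sim$observed, ids[sp$test]),
         metrics_grum = regressionMetrics(grum, sim$observed, ids[sp$test]))
  })
  .fixture_cache[[key]] <- runs
  runs
}
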