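# Scenario cache for the simulation-study tests. Power scenarios are
# expensive (2000 pairs each), so each is simulated and fitted once per
# test run and shared across test blocks.

.scenarioCache <- new.env(parent = emptyenv())

scenarioStudy <- function(name, ...) {
  key <- paste0("st_", name)
  if (!exists(key, .scenarioCache)) {
    cfg <- simConfig(n = 100, nSites = 2000, propTrue = 0.1, nSnps = 2000,
                     seed = 20259 + utf8ToInt(substr(name, 1, 1)), ...)
    assign(key, simulateStudy(cfg), .scenarioCache)
  }
  get(key, .scenarioCache)
}

scenarioPvalues <- function(name, method, ...) {
  key <- paste0("p_", name, "_", method)
  if (!exists(key, .scenarioCache)) {
    st <- scenarioStudy(name, ...)
    res <- fitStudy(st$pairs, st$K, method)
    assign(key, res$pvalue, .scenarioCache)
  }
  get(key, .scenarioCache)
}

scenarioPower <- function(name, method, alpha = 0.05, ...) {
  st <- scenarioStudy(name, ...)
  100 * powerAtFdr(scenarioPvalues(name, method, ...),
                   st$truth$is_mqtl, alpha)
}
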