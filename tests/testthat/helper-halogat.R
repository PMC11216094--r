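# Shared fixtures built once per test run. Featurization shells out to Open
# Babel, so cache the expensive objects instead of rebuilding them per test.

local_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = local_cache)) {
    assign(key, force(expr), envir = local_cache)
  }
  get(key, envir = local_cache)
}

homolytic_records <- function() cached("homo", bde_table("homolytic"))
heterolytic_records <- function() cached("hetero", bde_table("heterolytic"))
reagent_library <- function() cached("library", enumerate_reagents())
library_graphs <- function() {
  cached("graphs", mol_graphs(reagent_library()$smiles, descriptor_config(),
                              keys = reagent_library()$key))
}

toy_set <- function(n = 30, seed = 11) {
  cached(sprintf("toy_%d_%d", n, seed), {
    toy <- generate_toy_library(n, seed = seed)
    list(data = toy, graphs = mol_graphs(toy$smiles))
  })
}

# Closed-form simple-regression coefficients, independent of lm()
ols_normal_equations <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  intercept <- mean(y) - slope * mean(x)
  c(slope = slope, intercept = intercept)
}
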