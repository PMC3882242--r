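# Shared simulation runs, computed once per test session.
the_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(the_cache[[key]])) assign(key, force(expr), envir = the_cache)
  the_cache[[key]]
}

cached_run <- function(key, scenario) {
  cached(key, csd_simulate(scenario))
}

run_homogeneous <- function() {
  cached_run("homogeneous",
             make_scenario("homogeneous", snapshot_stride = 400L))
}

run_bypass <- function(F = 0.05) {
  cached_run(paste0("bypass", F), make_scenario("bypass", F = F))
}

run_slowdown <- function() {
  cached_run("slowdown", make_scenario("slowdown"))
}

run_three_waves <- function() {
  cached_run("three_waves", make_scenario("three_waves"))
}

run_spiral <- function() {
  cached_run("spiral", make_scenario("spiral"))
}

run_spiral_no_block <- function() {
  cached("spiral_no_block", {
    sc <- make_scenario("spiral")
    sc$blocks <- list()
    csd_simulate(sc)
  })
}
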