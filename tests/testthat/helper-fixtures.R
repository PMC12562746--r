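# Shared fixtures. Expensive objects (full baseline spectrum and its
# classified modes) are computed once per test run and cached.

# several acceptance expectations for the published table values are known
# to disagree (see the package vignette); keep the runner going so every
# suite still executes in full
options(testthat.progress.max_fails = 1000)

.cache <- new.env(parent = emptyenv())

baseline_stack <- function(n_a = 1.335, metal = "Ag") {
  key <- sprintf("stack_%s_%s", n_a, metal)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- build_baseline(n_a, metal = metal)
  .cache[[key]]
}

baseline_spectrum <- function() {
  if (is.null(.cache$spec))
    .cache$spec <- stack_spectrum(baseline_stack(), seq(750, 1100, by = 0.25))
  .cache$spec
}

baseline_modes <- function() {
  if (is.null(.cache$modes))
    .cache$modes <- classify_resonances(find_resonances(baseline_spectrum()))
  .cache$modes
}

enhanced_modes <- function() {
  if (is.null(.cache$emodes)) {
    sp <- stack_spectrum(build_enhanced(1.335), seq(750, 1100, by = 0.25))
    .cache$emodes <- classify_resonances(find_resonances(sp))
  }
  .cache$emodes
}

urine_sweep <- function() {
  if (is.null(.cache$usweep))
    .cache$usweep <- ri_sweep("baseline", glucose_map()$n_a)
  .cache$usweep
}

enhanced_sweep <- function() {
  if (is.null(.cache$esweep))
    .cache$esweep <- ri_sweep("enhanced", glucose_map()$n_a)
  .cache$esweep
}

# same stack traversed from the exit side
reverse_stack <- function(stack) {
  stack_spec(stack$exit_medium, rev(stack$layers), stack$incident_medium,
             analyte_index = stack$analyte_index)
}

# simple lossless two-layer toy used by several geometry/field tests
toy_stack <- function() {
  a <- material("a", constant_index(2.0))
  b <- material("b", constant_index(1.5))
  amb <- material("amb", constant_index(1.0))
  stack_spec(amb, list(layer(a, 100), layer(b, 200)), amb)
}
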