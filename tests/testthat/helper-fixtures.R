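# Shared fixtures, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# small deterministic reference reused by many tests
fixture_reference <- function(seed = 7L, length = 600L) {
  generate_reference(length, cpg_density = 0.04, gpc_density = 0.05,
                     seed = seed)
}

# a profile with hand-set GpC call states at given coordinates
fixture_gpc_profile <- function(pos, state) {
  data.frame(pos = as.integer(pos), state = state,
             stringsAsFactors = FALSE)
}

# population with exact class counts pushed through the perfect-chemistry
# protocol and the full call path
fixture_called_population <- function(ref, class_counts, classes = NULL,
                                      seed = 11L) {
  cls <- classes
  if (is.null(cls)) cls <- default_classes()
  spec <- population_spec(sum(unlist(class_counts)),
                          class_mix = unlist(class_counts),
                          classes = cls, seed = seed)
  pop <- generate_population(ref, spec)
  clones <- apply_assays(pop, ref, perfect_assay_params(), seed = seed + 1L)
  list(pop = pop, clones = clones,
       profiles = call_clones(clones, ref))
}

# random GpC state vector for footprint property tests
random_gpc_states <- function(n, p_acc = 0.5, p_undet = 0.15) {
  s <- sample(c("methylated", "unmethylated", "undetermined"), n,
              replace = TRUE,
              prob = c(p_acc * (1 - p_undet), (1 - p_acc) * (1 - p_undet),
                       p_undet))
  s
}
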