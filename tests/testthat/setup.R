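# Heavy shared fixtures, built lazily and cached for the whole run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# paper-scale-mini at mutation rate 0 (planted-gap recovery conditions)
mini_sim0 <- function() fixture("mini_sim0", function() {
  simulate_assembly_pair(sim_config(seed = 101, mutation_rate = 0))
})

mini_closure0 <- function() fixture("mini_closure0", function() {
  sim <- mini_sim0()
  gaps <- find_gaps(sim$target)
  flanks <- extract_flanks(sim$target, gaps, flank = 10000)
  alignments <- align_flanks(flanks, sim$donor)
  decisions <- extract_fills(evaluate_gaps(flanks, alignments, sim$donor),
                             flanks, sim$donor)
  list(gaps = gaps, flanks = flanks, alignments = alignments,
       decisions = decisions,
       result = apply_closures(sim$target, decisions, sim$donor))
})

# paper-scale-mini at the default 0.4% divergence
mini_sim <- function() fixture("mini_sim", function() {
  simulate_assembly_pair(sim_config(seed = 101))
})

mini_alignments <- function() fixture("mini_alignments", function() {
  sim <- mini_sim()
  gaps <- find_gaps(sim$target)
  flanks <- extract_flanks(sim$target, gaps, flank = 10000)
  list(gaps = gaps, flanks = flanks,
       alignments = align_flanks(flanks, sim$donor))
})
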