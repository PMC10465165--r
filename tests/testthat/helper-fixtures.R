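# shared fixtures: a compact protocol (20 s blocks, TR 2 s) keeps unit tests
# fast; acceptance tests use the full study protocol (30 s blocks, TR 1.5 s).

quick_design <- function(run_type = "training") {
  make_block_design(20, run_type)
}

quick_inputs <- function(design = quick_design(), TR = 2, bins = 8) {
  design_to_inputs(design, TR = TR, bins_per_tr = bins)
}

# memoised example subject + parameters (deterministic)
.fx <- new.env()

fx_params <- function(group = "learner", seed = 42) {
  key <- paste0(group, seed)
  if (is.null(.fx[[key]])) .fx[[key]] <- sample_subject_params(group, seed = seed)
  .fx[[key]]
}

# simple dcm_params with decoupled regions, for analytic checks
plain_params <- function(a_off = 0, c_gain = 0) {
  A <- diag(-0.5, 4)
  C <- matrix(0, 4, 1); C[1] <- c_gain
  dcm_params(A = A, C = C)
}

# protocol-scale design/inputs used by acceptance tests
protocol_design <- function(run_type = "training") make_block_design(30, run_type)
protocol_inputs <- function(design = protocol_design()) design_to_inputs(design)
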