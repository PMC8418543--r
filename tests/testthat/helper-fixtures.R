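# Cached fixtures and small helpers shared across test files.

fx_single <- builtin_fixture("base_single")
fx_semi <- builtin_fixture("base_semicontinuous")

res_single <- evaluate_scenario(fx_single)
res_semi <- evaluate_scenario(fx_semi)

# relative deviation helper
rel_dev <- function(x, ref) abs(x - ref) / abs(ref)
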