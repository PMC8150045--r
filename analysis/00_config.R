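# Shared configuration for the numbered analysis drivers.
# Source this from each script; set FINPAM_SEED in the environment to vary
# the realisation (default 1).

library(finpam)

analysis_seed <- as.integer(Sys.getenv("FINPAM_SEED", "1"))
analysis_config <- default_pipeline_config(outdir = "results/pipeline",
                                           seed = analysis_seed,
                                           days = 365L)
dir.create("results", showWarnings = FALSE)
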