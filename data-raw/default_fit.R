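# Regenerates the packaged default P-value parameters in R/stats.R
# (default_score_fit). Run after changing model defaults:
#   Rscript data-raw/default_fit.R
suppressPackageStartupMessages(library(tandemscan))
fit <- calibrate_scores(1e7, repeat_model(), seed = 101, winsize = 20000)
print(fit)
cat(sprintf("mu = %.10g, sigma = %.10g, omega = %.10g, n_regions = %d\n",
            fit$mu, fit$sigma, fit$omega, fit$n_regions))
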