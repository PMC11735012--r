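#!/usr/bin/env Rscript
# Thin command-line wrapper over strokeITE::run_full_analysis().
#
# Usage:
#   Rscript scripts/run_analysis.R --out <dir> [--cohort <csv>] [--n <int>]
#       [--seed <int>] [--estimators sps,ipw,dre] [--no-ite] [--no-mediation]
#
# Without --cohort, the default calibrated synthetic cohort of size --n is
# generated.

suppressMessages(library(strokeITE))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
has_flag <- function(flag) flag %in% args

seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", stop("--out <dir> is required"))
cohort_csv <- get_arg("--cohort")
n <- as.integer(get_arg("--n", "20000"))
estimators <- strsplit(get_arg("--estimators",
                               "naive,logistic-or,sps,ipw,dre,dml-linear,dml-nonlinear"),
                       ",")[[1L]]

cfg <- analysis_config(
  cohort = if (is.null(cohort_csv)) default_cohort_spec(n = n, seed = seed)
           else cohort_csv,
  estimators = estimators,
  mediation = !has_flag("--no-mediation"),
  ite = !has_flag("--no-ite"),
  out_dir = out,
  seed = seed,
  dragonnet = dragonnet_config(seed = seed),
  conformal = conformal_config(seed = seed))

res <- run_full_analysis(cfg)
print(res)
cat("\nbundle written to", out, "\n")
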