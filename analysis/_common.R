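# Shared setup for analysis steps 03-05: loads the analytic sample written
# by 02_score.R and the bundled comparator risk-score specifications.

suppressPackageStartupMessages(library(metsadd))

analytic <- read.csv("results/analytic.csv")

score_files <- c(framingham = "framingham_synthetic.yaml",
                 ascvd = "ascvd_synthetic.yaml",
                 bang = "bang_synthetic.yaml",
                 schmidt = "schmidt_synthetic.yaml")
scores <- lapply(score_files, function(f)
  read_risk_score_spec(system.file("extdata", f, package = "metsadd")))
outcomes <- c(framingham = "chd", ascvd = "chd",
              bang = "t2dm", schmidt = "t2dm")

# returns the outcome-appropriate data slice and the (standardized) score
score_data <- function(nm) {
  col <- standardize_score(compute_score(analytic, scores[[nm]]))
  dat <- analytic
  if (outcomes[[nm]] == "t2dm") {
    keep <- !is.na(dat$t2dm_10yr)
    dat <- dat[keep, , drop = FALSE]
    col$raw <- col$raw[keep]
    col$standardized <- col$standardized[keep]
    dat$outcome <- dat$t2dm_10yr
  }
  list(data = dat, col = col)
}
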