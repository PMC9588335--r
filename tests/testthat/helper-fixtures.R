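# Shared fixtures: the published shape estimates and a tiny hand-built
# cohort exercising every column of the schema.

published_params <- function() betabin_params(1.51, 1.15)

# explicit product form of the false-negative probability, kept separate
# from the log-gamma implementation as an independent oracle
p0_product <- function(n, alpha, beta) {
  vapply(n, function(m) {
    if (m == 0) return(1)
    prod((beta + 0:(m - 1)) / (alpha + beta + 0:(m - 1)))
  }, numeric(1))
}

tiny_cohort <- function() {
  data.frame(
    gender = c("male", "female", "female", "male"),
    age_group = c("<=45", ">45", "<=45", ">45"),
    ete = c("negative", "negative", "positive", "negative"),
    multifocal = c("no", "yes", "no", "no"),
    size_cat = c("<=1cm", "1-2cm", "missing", "2-4cm"),
    t_stage = c("T1", "T2", "T3", "T1"),
    nodes_examined = c(3L, 1L, 8L, 2L),
    nodes_positive = c(1L, 0L, 4L, 0L),
    followup_months = c(24.5, 60, 12.25, 48),
    event = c(1L, 0L, 1L, 0L),
    true_positive = c(TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}
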