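# shared fixture builders

uniform_bg <- function(order = 0L) {
  tabs <- lapply(0:order, function(o) matrix(0.25, nrow = 4^o, ncol = 4L))
  markov_background(order, tabs)
}

uniform_pwm <- function(id = "u", len = 2L) {
  pwm(id, matrix(0.25, 4L, len))
}

# strongly informative PWM with a fixed consensus
consensus_pwm <- function(id, consensus, dominant = 0.9) {
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix((1 - dominant) / 3, 4L, length(idx))
  m[cbind(idx, seq_along(idx))] <- dominant
  pwm(id, m)
}

random_pwm <- function(id, len) {
  m <- matrix(stats::rexp(4L * len), 4L, len)
  m <- sweep(m, 2L, colSums(m), "/")
  pwm(id, m)
}

# small model for oracle comparisons; parameters roomy enough that many
# segmentations carry mass
tiny_model <- function(pwms = list(uniform_pwm("a", 2L)),
                       p_r = 0.05, q0 = 0.3, h = 3, q = NULL,
                       corr = NULL, bg_order = 0L) {
  crm_model(pwms, theta0 = uniform_bg(bg_order),
            theta1 = uniform_bg(bg_order),
            p_r = p_r, q0 = q0, h = h, q = q, corr = corr)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
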