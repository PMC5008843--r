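# Shared fixtures: built-in models and small designs, constructed in code.

id_model <- builtin_model("immigration_death")
lv_model <- builtin_model("lotka_volterra")
ca_model <- builtin_model("calcium")

id_theta <- c(1, 0.1)
lv_theta <- c(0.5, 0.0025, 0.3)

# hand-coded rate-equation right-hand sides, independent of the package's
# expression machinery (oracles for the symbolic propensities)
id_rhs_manual <- function(x, th) th[1] - th[2] * x
lv_rhs_manual <- function(y, th) c(th[1] * y[1] - th[2] * y[1] * y[2],
                                   th[2] * y[1] * y[2] - th[3] * y[2])
ca_rhs_manual <- function(s, th) {
  ca <- s[1]; g <- s[2]; plc <- s[3]
  c(th[10] * g - th[11] * ca / (ca + th[12]),
    th[1] + th[2] * g - th[3] * g * ca / (g + th[4]) - th[5] * g * plc / (g + th[6]),
    th[7] * g - th[8] * plc / (plc + th[9]))
}
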