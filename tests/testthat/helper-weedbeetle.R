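# Fitted parameter values used across tests (printed precision)
table1 <- list(
  plant = c(lambda_B = 0.0027, lambda_G = 0.0948, lambda_D = 0.0014),
  leaf = c(r = 0.0238, b = 2.6786, mu_A = 0.0089, mu_J = 3.561,
           gamma_A = 0.0661, gamma_J = 0.0661),
  tip = c(r = 0.0143, b = 2.6786, mu_A = 0.0089, mu_J = 2.267,
          gamma_A = 0.0661, gamma_J = 0.0281),
  stem = c(r = 0.0130, b = 1.3393, mu_A = 0.0089, mu_J = 0.991,
           gamma_A = 0.0661, gamma_J = 0.0112),
  alpha = 10
)

# closed-form dominant eigenvalue oracles (kept independent of the
# package's eigen-routine implementations)
plant_lambda_closed <- function(lB, lG, lD) sqrt(lB * (lG - lD))
beetle_lambda_closed <- function(r, b, mu_A, mu_J) {
  # larger root of (x + r + mu_J)(x + mu_A) = r b
  a1 <- r + mu_J + mu_A
  a0 <- (r + mu_J) * mu_A - r * b
  (-a1 + sqrt(a1^2 - 4 * a0)) / 2
}

zero_beetle <- function() beetle_params(0, 0, 0, 0)
no_grazing <- function() interaction_params(0, 0, 0, 0, alpha = 10, mu_A2 = 0)
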