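# Substitution models: GTR family for DNA, two-state CTMC for binary
# (restriction-type) indel characters, both with discrete-gamma among-site
# rate variation (mean-normalised category rates at quantile medians).

#' DNA substitution model
#'
#' @param kind `"JC69"`, `"K80"`, `"HKY85"` or `"GTR"`.
#' @param rates 6 exchangeabilities in order AC, AG, AT, CG, CT, GT
#'   (rescaled so GT = 1 internally; ignored where the kind fixes them).
#' @param freqs base frequencies (A, C, G, T), summing to 1.
#' @param gamma use discrete-gamma rate variation?
#' @param alpha gamma shape (> 0).
#' @param ncat number of rate categories.
#' @return A list of class `subst_model`.
#' @export
subst_model <- function(kind = c("GTR", "JC69", "K80", "HKY85"),
                        rates = rep(1, 6), freqs = rep(0.25, 4),
                        gamma = TRUE, alpha = 0.5, ncat = 4L) {
  kind <- match.arg(kind)
  stopifnot(length(rates) == 6L, all(rates > 0),
            length(freqs) == 4L, abs(sum(freqs) - 1) < 1e-8,
            alpha > 0, ncat >= 1L)
  if (kind == "JC69") { rates <- rep(1, 6); freqs <- rep(0.25, 4) }
  if (kind == "K80") { rates <- c(1, rates[2], 1, 1, rates[2], 1); freqs <- rep(0.25, 4) }
  if (kind == "HKY85") rates <- c(1, rates[2], 1, 1, rates[2], 1)
  structure(list(kind = kind, rates = rates / rates[6], freqs = freqs,
                 gamma = gamma, alpha = alpha, ncat = as.integer(ncat)),
            class = "subst_model")
}

#' Binary (restriction-type) model for indel characters
#'
#' @param freqs stationary frequencies `(pi0, pi1)`.
#' @param gamma,alpha,ncat discrete-gamma settings as in [subst_model()].
#' @param conditioning `"variable"` conditions each character's likelihood
#'   on being variable (ascertainment correction, as for restriction data
#'   where constant characters cannot be observed); `"none"` disables it.
#' @return A list of class `binary_model`.
#' @export
binary_model <- function(freqs = c(0.5, 0.5), gamma = TRUE, alpha = 0.5,
                         ncat = 4L, conditioning = c("variable", "none")) {
  conditioning <- match.arg(conditioning)
  stopifnot(length(freqs) == 2L, abs(sum(freqs) - 1) < 1e-8, all(freqs > 0))
  structure(list(freqs = freqs, gamma = gamma, alpha = alpha,
                 ncat = as.integer(ncat), conditioning = conditioning),
            class = "binary_model")
}

#' Discrete-gamma category rates
#'
#' Quantile medians of the Gamma(alpha, alpha) distribution, one per
#' equal-probability category, normalised to mean 1.
#'
#' @param alpha shape parameter.
#' @param ncat number of categories.
#' @return Numeric vector of `ncat` rates with mean 1.
#' @export
gamma_rates <- function(alpha, ncat = 4L) {
  if (ncat == 1L) return(1)
  r <- qgamma((2 * seq_len(ncat) - 1) / (2 * ncat), shape = alpha, rate = alpha)
  r / mean(r)
}

.model_rates <- function(model) {
  if (isTRUE(model$gamma)) gamma_rates(model$alpha, model$ncat) else 1
}

# rate matrix Q (rows sum to 0) normalised to mean rate 1, for n-state
# reversible model with exchangeabilities and stationary frequencies
.q_matrix <- function(rates, freqs) {
  n <- length(freqs)
  Q <- matrix(0, n, n)
  if (n == 4L) {
    Q[1, 2] <- rates[1]; Q[1, 3] <- rates[2]; Q[1, 4] <- rates[3]
    Q[2, 3] <- rates[4]; Q[2, 4] <- rates[5]; Q[3, 4] <- rates[6]
    Q <- Q + t(Q)
  } else {                      # 2-state: single exchangeability
    Q[1, 2] <- Q[2, 1] <- 1
  }
  Q <- Q * rep(freqs, each = n)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

# eigendecomposition of Q for fast P(t); uses the pi-symmetrised form
.model_eigen <- function(model) {
  freqs <- model$freqs
  Q <- if (inherits(model, "binary_model")) .q_matrix(NULL, freqs)
       else .q_matrix(model$rates, freqs)
  sq <- sqrt(freqs)
  S <- Q * outer(sq, 1 / sq)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(vals = e$values,
       right = e$vectors / sq,       # rows scaled: diag(1/sq) %*% V
       left = t(e$vectors * sq),     # t(diag(sq) %*% V)
       freqs = freqs)
}

# transition probability matrix P(t) at rate r
.pmat <- function(eig, t, r = 1) {
  P <- eig$right %*% (exp(eig$vals * t * r) * eig$left)
  P[P < 0] <- 0
  P
}
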