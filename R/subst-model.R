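#' Amino-acid substitution models
#'
#' `substitution_model()` builds a time-reversible 20-state generator from a
#' symmetric exchangeability matrix and equilibrium frequencies.  The
#' generator is scaled so the expected substitution rate at equilibrium is 1,
#' i.e. branch lengths are in expected substitutions per site.  Transition
#' probabilities are computed from the eigendecomposition of the symmetrized
#' generator, which is exact for reversible models and done once per model.
#'
#' `jtt_model()` returns the JTT replacement model (Jones, Taylor & Thornton
#' 1992), the standard empirical matrix for globular proteins, read from the
#' numerical table shipped with the package.
#'
#' @param exchangeabilities symmetric 20x20 matrix of exchangeabilities
#'   (diagonal ignored), rows/cols in the order `A R N D C Q E G H I L K M F
#'   P S T W Y V`.
#' @param freqs equilibrium frequencies, length 20, same order; renormalized
#'   to sum to 1.
#' @return An object of class `subst_model` with elements `exchangeabilities`,
#'   `freqs`, `Q` (the scaled generator) and the eigendecomposition used by
#'   [transition_matrix()].
#' @export
substitution_model <- function(exchangeabilities, freqs) {
  stopifnot(is.matrix(exchangeabilities), dim(exchangeabilities) == c(20, 20),
            length(freqs) == 20, all(freqs > 0))
  s <- (exchangeabilities + t(exchangeabilities)) / 2
  pi <- freqs / sum(freqs)
  Q <- s * rep(pi, each = 20)      # Q[a,b] = s[a,b] * pi[b]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))         # expected rate at equilibrium
  Q <- Q / mu
  # symmetrized form D^{1/2} Q D^{-1/2} is symmetric for reversible Q
  sp <- sqrt(pi)
  Sym <- Q * (sp %o% (1 / sp))
  Sym <- (Sym + t(Sym)) / 2
  e <- eigen(Sym, symmetric = TRUE)
  structure(list(
    exchangeabilities = s,
    freqs = pi,
    Q = Q,
    evals = e$values,
    # P(t) = Avec %*% diag(exp(evals t)) %*% Binv
    Avec = e$vectors / sp,
    Binv = t(e$vectors) * rep(sp, each = 20)
  ), class = "subst_model")
}

#' @rdname substitution_model
#' @export
jtt_model <- function() {
  if (!is.null(.model_cache$jtt)) return(.model_cache$jtt)
  path <- system.file("extdata", "jtt.dat", package = "phylogp", mustWork = TRUE)
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(trimws(ln))]
  stopifnot(length(ln) == 20)
  ex <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (col in 1:19) {
    v <- scan(text = ln[col], quiet = TRUE)
    stopifnot(length(v) == 20 - col)
    ex[(col + 1):20, col] <- v
  }
  ex <- ex + t(ex)
  freqs <- scan(text = ln[20], quiet = TRUE)
  m <- substitution_model(ex, freqs)
  .model_cache$jtt <- m
  m
}

.model_cache <- new.env(parent = emptyenv())

#' Transition probability matrix
#'
#' @param model a [substitution_model()].
#' @param t branch length times rate (expected substitutions per site), >= 0.
#' @return 20x20 row-stochastic matrix `P[a, b] = P(state b at time t | a at 0)`.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "subst_model"), t >= 0)
  P <- model$Avec %*% (exp(model$evals * t) * model$Binv)
  # roundoff can leave tiny negatives; clamp, likelihoods must stay >= 0
  P[P < 0] <- 0
  P
}

#' @export
print.subst_model <- function(x, ...) {
  cat("Reversible amino-acid substitution model (20 states)\n")
  cat("  mean rate at equilibrium:",
      format(-sum(x$freqs * diag(x$Q))), "\n")
  cat("  frequencies:", paste0(AA_ALPHABET[1:5], "=",
                               signif(x$freqs[1:5], 3), collapse = " "), "...\n")
  invisible(x)
}
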