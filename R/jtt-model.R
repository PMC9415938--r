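# The Jones-Taylor-Thornton (JTT) empirical amino-acid substitution model.
# Exchangeabilities and equilibrium frequencies ship as plain text under
# inst/extdata/jtt_model.tsv; the rate matrix and its spectral decomposition
# are built once per session and cached.

.catyper_cache <- new.env(parent = emptyenv())

#' Load the JTT substitution model
#'
#' Parses the packaged JTT exchangeability/frequency table and returns the
#' normalised instantaneous rate matrix together with the spectral
#' decomposition used to evaluate transition probabilities
#' \eqn{P(t) = e^{Qt}} cheaply for many branch lengths.
#'
#' @return A list with elements `aa` (residue order), `freq` (equilibrium
#'   frequencies), `S` (symmetric exchangeabilities), `Q` (rate matrix scaled
#'   to one expected substitution per site per unit time), and `eig`
#'   (decomposition with `vec`, `inv`, `val`).
#' @export
jtt_model <- function() {
  if (!is.null(.catyper_cache$jtt)) return(.catyper_cache$jtt)
  path <- system.file("extdata", "jtt_model.tsv", package = "catyper",
                      mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  aa <- fields[[1]][-1]
  freq <- as.numeric(fields[[2]][-1])
  names(freq) <- aa
  freq <- freq / sum(freq)
  S <- matrix(0, 20, 20, dimnames = list(aa, aa))
  for (f in fields[-(1:2)]) {
    i <- match(f[[1]], aa)
    vals <- as.numeric(f[-1])
    S[i, seq_along(vals)] <- vals
  }
  S <- S + t(S)
  Q <- S %*% diag(freq)
  dimnames(Q) <- dimnames(S)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freq * diag(Q))
  Q <- Q / scale
  # reversible: symmetrise with pi^(1/2) to get a well-conditioned eigenproblem
  d <- sqrt(freq)
  B <- diag(d) %*% Q %*% diag(1 / d)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vec <- diag(1 / d) %*% e$vectors
  inv <- t(e$vectors) %*% diag(d)
  .catyper_cache$jtt <- list(aa = aa, freq = freq, S = S, Q = Q,
                             eig = list(vec = vec, inv = inv, val = e$values))
  .catyper_cache$jtt
}

# Transition probability matrix under JTT at branch length t.
jtt_prob <- function(t, model = jtt_model()) {
  e <- model$eig
  P <- e$vec %*% (exp(e$val * t) * e$inv)
  P[P < 1e-12] <- 1e-12
  dimnames(P) <- list(model$aa, model$aa)
  P
}
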