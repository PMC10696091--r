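#' Origin sequence models
#'
#' An origin model is an order-2 Markov chain over \{A, C, G, T\} used to
#' emit synthetic reference sequences of one origin class (human, viral or
#' bacterial). The three default models are compositionally divergent --
#' each class prefers different dinucleotide-to-base transitions -- which
#' gives the read classifier a learnable k-mer-like signature without
#' modeling real genomes. Each model is calibrated so that the stationary
#' GC fraction of emitted sequence equals its `gc_target`.
#'
#' @param label One of `"human"`, `"viral"`, `"bacterial"`.
#' @param transition A 16 x 4 row-stochastic matrix; rows are the 16
#'   dinucleotide contexts (`AA`, `AC`, ..., `TT`), columns the next base.
#' @param gc_target Intended stationary GC fraction in `[0, 1]`.
#' @return An object of class `origin_model`.
#' @export
origin_model <- function(label, transition, gc_target) {
  label <- match.arg(label, c("human", "viral", "bacterial"))
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(16L, 4L))) {
    stop("`transition` must be a 16 x 4 matrix (order-2 contexts x next base)")
  }
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-9)) {
    stop("every `transition` row must be non-negative and sum to 1 (tol 1e-9)")
  }
  if (gc_target < 0 || gc_target > 1) stop("`gc_target` must be in [0, 1]")
  rownames(transition) <- dinucleotide_contexts()
  colnames(transition) <- DNA_BASES
  structure(list(label = label, transition = transition, gc_target = gc_target),
            class = "origin_model")
}

dinucleotide_contexts <- function() {
  as.vector(outer(DNA_BASES, DNA_BASES, function(a, b) paste0(a, b)))
}

# Stationary distribution of the 16-state dinucleotide chain implied by a
# 16 x 4 context transition matrix, and the GC fraction it implies.
stationary_gc <- function(transition) {
  contexts <- dinucleotide_contexts()
  M <- matrix(0, 16, 16, dimnames = list(contexts, contexts))
  for (i in seq_len(16)) {
    b <- substr(contexts[i], 2, 2)
    for (k in seq_len(4)) {
      M[i, paste0(b, DNA_BASES[k])] <- transition[i, k]
    }
  }
  ev <- eigen(t(M))
  pi <- Re(ev$vectors[, which.max(Re(ev$values))])
  pi <- pi / sum(pi)
  names(pi) <- contexts
  last <- substr(contexts, 2, 2)
  list(pi = pi, gc = sum(pi[last %in% c("C", "G")]))
}

# Reweight each row of a preference matrix toward/away from G+C by a
# scalar tilt, chosen by root finding so the stationary GC hits `target`.
calibrate_gc <- function(preference, target) {
  s <- ifelse(DNA_BASES %in% c("C", "G"), 1, -1)
  tilt <- function(theta) {
    t <- sweep(preference, 2, exp(theta * s), `*`)
    t / rowSums(t)
  }
  f <- function(theta) stationary_gc(tilt(theta))$gc - target
  theta <- stats::uniroot(f, c(-6, 6), tol = 1e-10)$root
  tilt(theta)
}

#' Default divergent origin models
#'
#' Three order-2 Markov models whose transition preferences are
#' well-separated: the human-like model depletes CpG and mildly favors
#' repeating the previous base; the viral-like model is AT-rich with
#' strong homopolymer runs; the bacterial-like model is GC-rich and
#' favors a cyclic A->C->G->T->A transition. Sharpness controls how
#' concentrated each row is and hence how separable the classes are.
#'
#' @param sharpness Weight placed on each row's preferred base before GC
#'   calibration; larger values give more divergent (more learnable)
#'   classes. Default 6.
#' @return Named list of three `origin_model` objects.
#' @export
default_origin_models <- function(sharpness = 6) {
  contexts <- dinucleotide_contexts()
  prev <- substr(contexts, 2, 2)
  base_idx <- function(b) match(b, DNA_BASES)

  pref <- function(favored, avoid = NULL) {
    m <- matrix(1, 16, 4, dimnames = list(contexts, DNA_BASES))
    for (i in seq_len(16)) m[i, favored[i]] <- sharpness
    if (!is.null(avoid)) for (i in seq_len(16)) {
      if (!is.na(avoid[i])) m[i, avoid[i]] <- 0.15
    }
    m / rowSums(m)
  }

  # human-like: repeat previous base, deplete G after C (CpG depletion)
  human_fav <- base_idx(prev)
  human_avoid <- ifelse(prev == "C", base_idx("G"), NA_integer_)
  # viral-like: homopolymer runs biased to A/T
  viral_fav <- ifelse(prev %in% c("A", "T"), base_idx(prev), base_idx("A"))
  # bacterial-like: cyclic walk A->C->G->T->A
  cyc <- c(A = "C", C = "G", G = "T", T = "A")
  bact_fav <- base_idx(cyc[prev])

  list(
    human = origin_model("human",
                         calibrate_gc(pref(human_fav, human_avoid), 0.45), 0.45),
    viral = origin_model("viral", calibrate_gc(pref(viral_fav), 0.38), 0.38),
    bacterial = origin_model("bacterial", calibrate_gc(pref(bact_fav), 0.62), 0.62)
  )
}

# Emit `n` sequences of the given lengths from an origin model.
# Vectorized across sequences: one pass over positions, each step sampling
# the next base for every sequence from its context row.
markov_sequences <- function(model, lengths) {
  n <- length(lengths)
  if (n == 0L) return(character(0))
  tr <- model$transition
  cum <- t(apply(tr, 1, cumsum))
  pi <- stationary_gc(tr)$pi
  maxlen <- max(lengths)
  out <- matrix("", nrow = n, ncol = maxlen)
  # initial dinucleotide context from the stationary distribution
  ctx <- sample.int(16L, n, replace = TRUE, prob = pi)
  contexts <- dinucleotide_contexts()
  out[, 1] <- substr(contexts[ctx], 1, 1)
  out[, 2] <- substr(contexts[ctx], 2, 2)
  if (maxlen >= 3) for (p in 3:maxlen) {
    alive <- lengths >= p
    if (!any(alive)) break
    u <- stats::runif(n)
    nxt <- 1L + rowSums(cum[ctx, , drop = FALSE] < u)
    out[alive, p] <- DNA_BASES[nxt[alive]]
    # context index is a + 4*(b-1) for dinucleotide (a, b); the new context
    # is (old last base, newly emitted base)
    b <- (ctx - 1L) %/% 4L + 1L
    ctx <- ifelse(alive, b + 4L * (nxt - 1L), ctx)
  }
  vapply(seq_len(n), function(i) paste(out[i, seq_len(lengths[i])], collapse = ""),
         character(1))
}
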