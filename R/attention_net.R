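#' Hyperparameters of the attention-network classifier
#'
#' The classifier stacks four learned stages: a token embedding, a 1-D
#' convolution (kernel width 3, same padding), a bidirectional tanh
#' recurrence, and additive attention pooling feeding a sigmoid output. The
#' additive attention scorer sees both the recurrent state and the local
#' convolution feature at each position, so attention concentrates on
#' locally informative tokens rather than on the sequence summary alone.
#' Sizes are deliberately small for single-core CPU training. Tokens beyond
#' `max_tokens` are truncated; a vocabulary larger than `vocab_cap` is a
#' configuration error.
#'
#' @param d_embed Embedding dimension.
#' @param d_conv Number of convolution filters.
#' @param d_hidden Recurrent hidden size per direction.
#' @param d_attn Additive-attention projection size.
#' @param max_tokens Per-section token truncation.
#' @param vocab_cap Maximum admissible vocabulary size.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @return A named list of hyperparameters.
#' @export
attention_hyper <- function(d_embed = 32L, d_conv = 64L, d_hidden = 32L,
                            d_attn = 32L, max_tokens = 256L,
                            vocab_cap = 20000L, epochs = 5L,
                            batch_size = 32L, learning_rate = 0.01) {
  list(d_embed = d_embed, d_conv = d_conv, d_hidden = d_hidden,
       d_attn = d_attn, max_tokens = max_tokens, vocab_cap = vocab_cap,
       epochs = epochs, batch_size = batch_size,
       learning_rate = learning_rate)
}

add_bias <- function(m, b) m + matrix(b, nrow(m), length(b), byrow = TRUE)

init_attention_params <- function(n_vocab, h) {
  rn <- function(r, c) matrix(stats::rnorm(r * c, sd = 0.1), r, c)
  list(E = rn(n_vocab + 1L, h$d_embed),        # + 1 row for unknown tokens
       Wc = rn(3L * h$d_embed, h$d_conv), bc = numeric(h$d_conv),
       Wf = rn(h$d_conv, h$d_hidden), Uf = rn(h$d_hidden, h$d_hidden),
       bf = numeric(h$d_hidden),
       Wb = rn(h$d_conv, h$d_hidden), Ub = rn(h$d_hidden, h$d_hidden),
       bb = numeric(h$d_hidden),
       Wa = rn(2L * h$d_hidden, h$d_attn), Wl = rn(h$d_conv, h$d_attn),
       ba = numeric(h$d_attn),
       va = stats::rnorm(h$d_attn, sd = 0.1),
       wo = stats::rnorm(2L * h$d_hidden, sd = 0.1), bo = 0)
}

tokens_to_ids <- function(tokens, vocab, max_tokens) {
  ids <- match(tokens, vocab)
  ids[is.na(ids)] <- length(vocab) + 1L           # unknown-token row
  if (length(ids) > max_tokens) ids <- ids[seq_len(max_tokens)]
  if (length(ids) == 0L) ids <- length(vocab) + 1L
  ids
}

pad_batch <- function(id_list) {
  lens <- lengths(id_list)
  T <- max(lens)
  B <- length(id_list)
  ids <- matrix(1L, B, T)
  mask <- matrix(0, B, T)
  for (i in seq_len(B)) {
    ids[i, seq_len(lens[i])] <- id_list[[i]]
    mask[i, seq_len(lens[i])] <- 1
  }
  list(ids = ids, mask = mask)
}

attn_forward <- function(params, ids, mask, h) {
  B <- nrow(ids); T <- ncol(ids)
  de <- h$d_embed; dh <- h$d_hidden
  zero_e <- matrix(0, B, de)
  X <- vector("list", T)
  for (t in seq_len(T)) {
    xt <- params$E[ids[, t], , drop = FALSE]
    X[[t]] <- mask[, t] * xt
  }
  Ccat <- vector("list", T); C <- vector("list", T)
  for (t in seq_len(T)) {
    left <- if (t > 1L) X[[t - 1L]] else zero_e
    right <- if (t < T) X[[t + 1L]] else zero_e
    Ccat[[t]] <- cbind(left, X[[t]], right)
    pre <- add_bias(Ccat[[t]] %*% params$Wc, params$bc)
    C[[t]] <- mask[, t] * pmax(pre, 0)
  }
  Hf <- vector("list", T); Hf_t <- vector("list", T)
  hprev <- matrix(0, B, dh)
  for (t in seq_len(T)) {
    z <- add_bias(C[[t]] %*% params$Wf + hprev %*% params$Uf, params$bf)
    Hf_t[[t]] <- tanh(z)
    Hf[[t]] <- mask[, t] * Hf_t[[t]] + (1 - mask[, t]) * hprev
    hprev <- Hf[[t]]
  }
  Hb <- vector("list", T); Hb_t <- vector("list", T)
  hnext <- matrix(0, B, dh)
  for (t in rev(seq_len(T))) {
    z <- add_bias(C[[t]] %*% params$Wb + hnext %*% params$Ub, params$bb)
    Hb_t[[t]] <- tanh(z)
    Hb[[t]] <- mask[, t] * Hb_t[[t]] + (1 - mask[, t]) * hnext
    hnext <- Hb[[t]]
  }
  A <- vector("list", T); U <- vector("list", T)
  escore <- matrix(-1e30, B, T)
  for (t in seq_len(T)) {
    A[[t]] <- cbind(Hf[[t]], Hb[[t]])
    U[[t]] <- tanh(add_bias(A[[t]] %*% params$Wa + C[[t]] %*% params$Wl,
                            params$ba))
    escore[, t] <- as.vector(U[[t]] %*% params$va)
  }
  escore[mask == 0] <- -1e30
  emax <- apply(escore, 1, max)
  ex <- exp(escore - emax) * mask
  alpha <- ex / rowSums(ex)
  context <- matrix(0, B, 2L * dh)
  for (t in seq_len(T)) context <- context + alpha[, t] * A[[t]]
  logit <- as.vector(context %*% params$wo) + params$bo
  p <- stats::plogis(logit)
  list(ids = ids, mask = mask, X = X, Ccat = Ccat, C = C,
       Hf = Hf, Hf_t = Hf_t, Hb = Hb, Hb_t = Hb_t,
       A = A, U = U, alpha = alpha, context = context, p = p)
}

attn_backward <- function(params, fw, y, h) {
  B <- nrow(fw$ids); T <- ncol(fw$ids)
  de <- h$d_embed; dh <- h$d_hidden
  g <- lapply(params, function(p) p * 0)
  dlogit <- (fw$p - y) / B
  g$wo <- as.vector(t(fw$context) %*% dlogit)
  g$bo <- sum(dlogit)
  dcontext <- outer(dlogit, params$wo)
  dA <- vector("list", T)
  dalpha <- matrix(0, B, T)
  for (t in seq_len(T)) {
    dA[[t]] <- fw$alpha[, t] * dcontext
    dalpha[, t] <- rowSums(dcontext * fw$A[[t]])
  }
  srow <- rowSums(fw$alpha * dalpha)
  de_score <- fw$alpha * (dalpha - srow)
  dCattn <- vector("list", T)
  for (t in seq_len(T)) {
    dscore <- de_score[, t]
    g$va <- g$va + as.vector(t(fw$U[[t]]) %*% dscore)
    dpre <- outer(dscore, params$va) * (1 - fw$U[[t]]^2)
    g$Wa <- g$Wa + t(fw$A[[t]]) %*% dpre
    g$Wl <- g$Wl + t(fw$C[[t]]) %*% dpre
    g$ba <- g$ba + colSums(dpre)
    dA[[t]] <- dA[[t]] + dpre %*% t(params$Wa)
    dCattn[[t]] <- dpre %*% t(params$Wl)
  }
  dC <- vector("list", T)
  for (t in seq_len(T)) dC[[t]] <- dCattn[[t]]
  carry <- matrix(0, B, dh)
  for (t in rev(seq_len(T))) {
    gh <- dA[[t]][, seq_len(dh), drop = FALSE] + carry
    m <- fw$mask[, t]
    dt <- (m * gh) * (1 - fw$Hf_t[[t]]^2)
    hprev <- if (t > 1L) fw$Hf[[t - 1L]] else matrix(0, B, dh)
    g$Wf <- g$Wf + t(fw$C[[t]]) %*% dt
    g$Uf <- g$Uf + t(hprev) %*% dt
    g$bf <- g$bf + colSums(dt)
    dC[[t]] <- dC[[t]] + dt %*% t(params$Wf)
    carry <- dt %*% t(params$Uf) + (1 - m) * gh
  }
  carry <- matrix(0, B, dh)
  for (t in seq_len(T)) {
    gh <- dA[[t]][, dh + seq_len(dh), drop = FALSE] + carry
    m <- fw$mask[, t]
    dt <- (m * gh) * (1 - fw$Hb_t[[t]]^2)
    hnext <- if (t < T) fw$Hb[[t + 1L]] else matrix(0, B, dh)
    g$Wb <- g$Wb + t(fw$C[[t]]) %*% dt
    g$Ub <- g$Ub + t(hnext) %*% dt
    g$bb <- g$bb + colSums(dt)
    dC[[t]] <- dC[[t]] + dt %*% t(params$Wb)
    carry <- dt %*% t(params$Ub) + (1 - m) * gh
  }
  dX <- vector("list", T)
  for (t in seq_len(T)) dX[[t]] <- matrix(0, B, de)
  for (t in seq_len(T)) {
    dpre <- dC[[t]] * (fw$C[[t]] > 0)
    g$Wc <- g$Wc + t(fw$Ccat[[t]]) %*% dpre
    g$bc <- g$bc + colSums(dpre)
    dcat <- dpre %*% t(params$Wc)
    if (t > 1L) dX[[t - 1L]] <- dX[[t - 1L]] + dcat[, seq_len(de),
                                                    drop = FALSE]
    dX[[t]] <- dX[[t]] + dcat[, de + seq_len(de), drop = FALSE]
    if (t < T) dX[[t + 1L]] <- dX[[t + 1L]] + dcat[, 2L * de + seq_len(de),
                                                   drop = FALSE]
  }
  rows <- do.call(rbind, lapply(seq_len(T), function(t) {
    fw$mask[, t] * dX[[t]]
  }))
  idvec <- as.vector(fw$ids)
  agg <- rowsum(rows, group = idvec)
  g$E[as.integer(rownames(agg)), ] <- g$E[as.integer(rownames(agg)), ,
                                          drop = FALSE] + agg
  g
}

adam_step <- function(params, grads, state, lr, step,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^step)
    vhat <- state$v[[nm]] / (1 - b2^step)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the attention-network baseline
#'
#' Trains the four-stage classifier (token embedding, 1-D convolution,
#' bidirectional tanh recurrence, additive attention pooling into a sigmoid
#' output) by minibatch Adam on the binary cross-entropy. Training is fully
#' seeded; the fitted model exposes per-token attention weights via
#' [attention_trace()].
#'
#' @param corpus A `note_corpus` containing both classes.
#' @param hyper Hyperparameters, see [attention_hyper()].
#' @param seed Integer seed.
#' @return An `attention_net_model`.
#' @export
train_attention_net <- function(corpus, hyper = attention_hyper(),
                                seed = 1L) {
  if (length(unique(corpus$label)) < 2L) {
    stop("corpus contains a single class; cannot train", call. = FALSE)
  }
  toks <- tokenize_text(corpus$text)
  vocab <- sort(unique(unlist(toks)), method = "radix")
  if (length(vocab) > hyper$vocab_cap) {
    stop("vocabulary size ", length(vocab), " overflows the configured cap ",
         hyper$vocab_cap, call. = FALSE)
  }
  id_list <- lapply(toks, tokens_to_ids, vocab = vocab,
                    max_tokens = hyper$max_tokens)
  y_all <- corpus$label
  n <- length(id_list)
  set.seed(seed)
  params <- init_attention_params(length(vocab), hyper)
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  step <- 0L
  for (epoch in seq_len(hyper$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = hyper$batch_size)
    for (s in starts) {
      batch <- ord[s:min(s + hyper$batch_size - 1L, n)]
      pb <- pad_batch(id_list[batch])
      fw <- attn_forward(params, pb$ids, pb$mask, hyper)
      grads <- attn_backward(params, fw, y_all[batch], hyper)
      step <- step + 1L
      upd <- adam_step(params, grads, state, hyper$learning_rate, step)
      params <- upd$params
      state <- upd$state
    }
  }
  structure(list(params = params, vocabulary = vocab, hyper = hyper,
                 seed = seed),
            class = "attention_net_model")
}

#' @export
predict_score.attention_net_model <- function(model, corpus) {
  toks <- tokenize_text(corpus$text)
  id_list <- lapply(toks, tokens_to_ids, vocab = model$vocabulary,
                    max_tokens = model$hyper$max_tokens)
  n <- length(id_list)
  out <- numeric(n)
  starts <- seq(1L, n, by = 64L)
  for (s in starts) {
    batch <- s:min(s + 63L, n)
    pb <- pad_batch(id_list[batch])
    fw <- attn_forward(model$params, pb$ids, pb$mask, model$hyper)
    out[batch] <- fw$p
  }
  out
}

#' Per-token attention weights for one section
#'
#' The softmax attention weights the fitted model assigns to each token of
#' the (truncated) section; non-negative and summing to 1.
#'
#' @param model An `attention_net_model`.
#' @param text A single section text.
#' @return Named numeric vector of attention weights, one per token.
#' @export
attention_trace <- function(model, text) {
  if (!inherits(model, "attention_net_model")) {
    stop("attention traces require a fitted attention_net_model",
         call. = FALSE)
  }
  toks <- tokenize_text(text)[[1]]
  if (length(toks) > model$hyper$max_tokens) {
    toks <- toks[seq_len(model$hyper$max_tokens)]
  }
  if (length(toks) == 0L) {
    warning("section has no tokens; empty attention trace")
    return(stats::setNames(numeric(0), character(0)))
  }
  ids <- tokens_to_ids(toks, model$vocabulary, model$hyper$max_tokens)
  pb <- pad_batch(list(ids))
  fw <- attn_forward(model$params, pb$ids, pb$mask, model$hyper)
  stats::setNames(as.vector(fw$alpha)[seq_along(toks)], toks)
}
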