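# The multiscale surface transformer. Input signals on an order-n icosphere
# are tokenised by the order-(n-1) patch grid, embedded with learned positional
# vectors, and processed through up to four encoder levels. Each level projects
# to a 2^(l-1) * D embedding, applies windowed + shifted-window attention
# blocks, and merges sibling patches 4-to-1 (omitted at the last level). A
# mean-pooled linear head serves regression/classification; a U-shaped decoder
# with skip connections and 1-to-4 patch partition serves vertex-wise
# segmentation.

#' Model configuration
#'
#' Level `l` embeds tokens in `2^(l-1) * base_dim` dimensions; window sizes are
#' fixed by the icosphere hierarchy (faces of the mesh `window_depth` levels
#' below the sequence grid, 64 patches per window at the default depth 3, one
#' global window when no such mesh exists — for a 6th-order input this makes
#' level 4 global over the 320 order-2 faces). The default depths/heads follow
#' a compact Swin-style parameterisation.
#'
#' @param task `"regression"`, `"classification"` or `"segmentation"`.
#' @param input_order Order of the input icosphere (default 6).
#' @param channels Number of input channels C.
#' @param base_dim Embedding dimension D of the first level.
#' @param depths Integer vector, local-MHSA blocks per level (length = number
#'   of levels, at most 4).
#' @param heads Attention heads per level; `2^(l-1) * base_dim` must be
#'   divisible by `heads[l]`.
#' @param mlp_ratio Hidden width of each FFN as a multiple of the embedding.
#' @param dropout Dropout probability applied to the embedded input sequence
#'   during training.
#' @param shift_fraction Fraction of the window size the shifted-attention
#'   pass rolls by (default 0.5 — half the patches of each window).
#' @param window_depth Subdivision gap between sequence grid and window grid.
#' @param num_outputs Output dimension of the regression/classification head.
#' @param num_classes Number of classes for segmentation (>= 2).
#' @param decoder_depths Local-MHSA blocks per decoder level (length
#'   `length(depths) - 1`; 0 = projection-only decoding).
#' @return An object of class `mssit_config`.
#' @export
mssit_config <- function(task = c("regression", "classification", "segmentation"),
                         input_order = 6, channels = 4, base_dim = 96,
                         depths = c(2, 2, 6, 2), heads = c(3, 6, 12, 24),
                         mlp_ratio = 4, dropout = 0, shift_fraction = 0.5,
                         window_depth = 3, num_outputs = 1,
                         num_classes = NULL,
                         decoder_depths = rep(0L, max(length(depths) - 1L, 0L))) {
  task <- match.arg(task)
  n_levels <- length(depths)
  if (n_levels < 1 || n_levels > 4)
    stop("between 1 and 4 encoder levels are supported")
  if (length(heads) != n_levels)
    stop("`heads` must have one entry per level")
  if (input_order - n_levels < 0)
    stop("`input_order` is too small for the requested number of levels")
  dims <- 2^(seq_len(n_levels) - 1) * base_dim
  if (any(dims %% heads != 0))
    stop("every level's embedding dim must be divisible by its head count")
  if (task == "segmentation") {
    if (is.null(num_classes) || num_classes < 2)
      stop("segmentation needs `num_classes` >= 2")
    if (length(decoder_depths) != n_levels - 1L)
      stop("`decoder_depths` must have one entry per decoder level")
  }
  out <- list(task = task, input_order = as.integer(input_order),
              channels = as.integer(channels), base_dim = as.integer(base_dim),
              depths = as.integer(depths), heads = as.integer(heads),
              mlp_ratio = mlp_ratio, dropout = dropout,
              shift_fraction = shift_fraction,
              window_depth = as.integer(window_depth),
              num_outputs = as.integer(num_outputs),
              num_classes = if (is.null(num_classes)) NULL else as.integer(num_classes),
              decoder_depths = as.integer(decoder_depths),
              n_levels = n_levels, dims = as.integer(dims))
  class(out) <- "mssit_config"
  out
}

.config_geometry <- function(config) {
  n <- config$input_order
  wmaps <- lapply(seq_len(config$n_levels), function(l)
    build_window_map(l, config$shift_fraction, input_order = n,
                     window_depth = config$window_depth))
  fine <- build_icosphere(n)
  coarse <- build_icosphere(n - 1L)
  list(wmaps = wmaps,
       partition = build_patch_partition(fine, coarse),
       n_vertices = nrow(fine$vertices),
       seq_lens = vapply(wmaps, `[[`, integer(1), "seq_len"))
}

# ---- parameter initialisation ----------------------------------------------

.init_linear <- function(d_in, d_out) {
  r <- 1 / sqrt(d_in)
  list(W = matrix(stats::runif(d_in * d_out, -r, r), d_in, d_out),
       b = rep(0, d_out))
}
.init_ln <- function(d) list(g = rep(1, d), b = rep(0, d))
.init_attn <- function(d) {
  r <- 1 / sqrt(d)
  U <- function() matrix(stats::runif(d * d, -r, r), d, d)
  list(Wq = U(), Wk = U(), Wv = U(), Wo = U(),
       bq = rep(0, d), bk = rep(0, d), bv = rep(0, d), bo = rep(0, d))
}
.init_ffn <- function(d, ratio) {
  h <- round(d * ratio)
  l1 <- .init_linear(d, h); l2 <- .init_linear(h, d)
  list(W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b)
}
.init_block <- function(d, ratio) {
  list(ln1 = .init_ln(d), attn1 = .init_attn(d),
       ln2 = .init_ln(d), ffn1 = .init_ffn(d, ratio),
       ln3 = .init_ln(d), attn2 = .init_attn(d),
       ln4 = .init_ln(d), ffn2 = .init_ffn(d, ratio))
}

#' Initialise model parameters
#'
#' Weight matrices use a symmetric uniform fan-in scheme, biases start at zero,
#' positional embeddings at N(0, 0.02), LayerNorm gains at one.
#'
#' @param config An [mssit_config()].
#' @param seed Integer seed making initialisation reproducible.
#' @return A nested list of parameter arrays.
#' @export
init_mssit_params <- function(config, seed = 0L) {
  set.seed(seed)
  geo <- .config_geometry(config)
  d_in <- config$channels * 6L
  L0 <- geo$seq_lens[1]
  params <- list(
    pos_emb = matrix(stats::rnorm(L0 * d_in, 0, 0.02), L0, d_in),
    in_ln = .init_ln(d_in),
    levels = vector("list", config$n_levels)
  )
  d_prev <- d_in
  for (l in seq_len(config$n_levels)) {
    d_l <- config$dims[l]
    lev <- list(proj = .init_linear(d_prev, d_l),
                blocks = lapply(seq_len(config$depths[l]), function(i)
                  .init_block(d_l, config$mlp_ratio)))
    params$levels[[l]] <- lev
    d_prev <- 4L * d_l      # post-merge concatenated dimension
  }
  d_last <- config$dims[config$n_levels]
  if (config$task %in% c("regression", "classification")) {
    params$head <- .init_linear(d_last, config$num_outputs)
  } else {
    nl <- config$n_levels
    params$decoder <- vector("list", nl - 1L)
    d_up <- d_last
    for (i in seq_len(nl - 1L)) {
      l <- nl - i                      # decoder step up to encoder level l
      d_l <- config$dims[l]
      dec <- list(proj = .init_linear(d_up + d_l, d_l))
      if (config$decoder_depths[i] > 0)
        dec$blocks <- lapply(seq_len(config$decoder_depths[i]), function(j)
          .init_block(d_l, config$mlp_ratio))
      params$decoder[[i]] <- dec
      d_up <- d_l
    }
    params$seg_head <- .init_linear(config$dims[1], 6L * config$num_classes)
  }
  params
}

# ---- tokenisation -----------------------------------------------------------

#' Tokenise a surface signal into patch tokens
#'
#' Token `i` gathers the 6 patch-vertex values of coarse face `i` (corners then
#' midpoints) for each channel and concatenates across channels, giving a
#' `|F_coarse| x (6 C)` sequence.
#'
#' @param signal A [surface_signal()] on the partition's fine mesh.
#' @param partition A [build_patch_partition()] result.
#' @return `L x (6 C)` matrix of patch tokens.
#' @export
tokenize <- function(signal, partition) {
  stopifnot(inherits(signal, "surface_signal"),
            inherits(partition, "patch_partition"))
  ids <- partition$patch_vertex_ids
  n_fine <- 10 * 4^partition$fine_order + 2
  if (nrow(signal$values) != n_fine)
    stop(sprintf("signal has %d rows but the order-%d partition needs %d",
                 nrow(signal$values), partition$fine_order, n_fine))
  C <- ncol(signal$values)
  cols <- lapply(seq_len(C), function(ch)
    matrix(signal$values[ids + 1L, ch], nrow(ids), 6L))
  do.call(cbind, cols)
}

# ---- encoder ----------------------------------------------------------------

.encoder_fwd <- function(params, X0, config, geo, train = FALSE,
                         keep_attention = FALSE) {
  cache <- list()
  x <- X0 + params$pos_emb
  ln_in <- .ln_fwd(x, params$in_ln$g, params$in_ln$b)
  cache$x_pre_ln <- x
  cache$ln_in <- ln_in
  x <- ln_in$y
  drop_mask <- NULL
  if (train && config$dropout > 0) {
    drop_mask <- matrix(stats::rbinom(length(x), 1, 1 - config$dropout) /
                          (1 - config$dropout), nrow(x), ncol(x))
    x <- x * drop_mask
  }
  cache$drop_mask <- drop_mask
  skips <- vector("list", config$n_levels)
  lev_cache <- vector("list", config$n_levels)
  attn_maps <- if (keep_attention) vector("list", config$n_levels) else NULL
  for (l in seq_len(config$n_levels)) {
    lp <- params$levels[[l]]
    lc <- list(x_in = x)
    x <- .linear_fwd(x, lp$proj$W, lp$proj$b)
    lc$blocks <- vector("list", length(lp$blocks))
    if (keep_attention) attn_maps[[l]] <- vector("list", length(lp$blocks))
    for (bidx in seq_along(lp$blocks)) {
      lc$blocks[[bidx]]$x_in <- x
      bf <- .block_fwd(x, lp$blocks[[bidx]], geo$wmaps[[l]], config$heads[l],
                       keep_attention)
      lc$blocks[[bidx]]$cache <- bf$cache
      if (keep_attention)
        attn_maps[[l]][[bidx]] <- list(windowed = bf$cache$a1$attention,
                                       shifted = bf$cache$a2$attention)
      x <- bf$y
    }
    skips[[l]] <- x
    lc$x_out <- x
    lev_cache[[l]] <- lc
    if (l < config$n_levels) x <- .merge_fwd(x)
  }
  list(x = x, skips = skips, cache = cache, lev_cache = lev_cache,
       attention = attn_maps)
}

.encoder_bwd <- function(params, config, geo, enc, dx, dskips = NULL) {
  grads <- list(levels = vector("list", config$n_levels))
  for (l in rev(seq_len(config$n_levels))) {
    lp <- params$levels[[l]]
    lc <- enc$lev_cache[[l]]
    if (l < config$n_levels) dx <- .merge_bwd(dx, config$dims[l])
    if (!is.null(dskips) && !is.null(dskips[[l]])) dx <- dx + dskips[[l]]
    gb <- vector("list", length(lp$blocks))
    for (bidx in rev(seq_along(lp$blocks))) {
      bb <- .block_bwd(lc$blocks[[bidx]]$cache, lp$blocks[[bidx]],
                       lc$blocks[[bidx]]$x_in, dx)
      gb[[bidx]] <- bb$grads
      dx <- bb$dx
    }
    gl <- .linear_bwd(lc$x_in, lp$proj$W, dx)
    grads$levels[[l]] <- list(proj = list(W = gl$dW, b = gl$db), blocks = gb)
    dx <- gl$dx
  }
  if (!is.null(enc$cache$drop_mask)) dx <- dx * enc$cache$drop_mask
  lin <- .ln_bwd(enc$cache$ln_in, params$in_ln$g, dx)
  grads$in_ln <- list(g = lin$dg, b = lin$db)
  grads$pos_emb <- lin$dx
  grads
}

# ---- task forwards ----------------------------------------------------------

#' Forward pass of the regression/classification network
#'
#' Tokenise, add positional embeddings (LayerNorm + dropout), run the encoder
#' levels, average the final token sequence into a single token and apply the
#' linear head.
#'
#' @param signal A [surface_signal()] on the configured input icosphere.
#' @param config An [mssit_config()] with task regression/classification.
#' @param params Parameters from [init_mssit_params()] (or a trained model).
#' @param keep_attention Return per-window attention weight tables as the
#'   `attention` attribute.
#' @return Numeric vector of length `num_outputs`.
#' @export
forward_regression <- function(signal, config, params, keep_attention = FALSE) {
  if (!config$task %in% c("regression", "classification"))
    stop("`config$task` must be regression or classification")
  geo <- .config_geometry(config)
  fw <- .forward_reg_full(signal, config, params, geo,
                          keep_attention = keep_attention)
  out <- fw$pred
  if (keep_attention) attr(out, "attention") <- fw$enc$attention
  out
}

.forward_reg_full <- function(signal, config, params, geo, train = FALSE,
                              keep_attention = FALSE) {
  X0 <- tokenize(signal, geo$partition)
  enc <- .encoder_fwd(params, X0, config, geo, train, keep_attention)
  pooled <- colMeans(enc$x)
  pred <- as.vector(crossprod(params$head$W, pooled) + params$head$b)
  list(pred = pred, pooled = pooled, enc = enc)
}

.backward_reg_full <- function(config, geo, params, fw, dpred) {
  L_last <- nrow(fw$enc$x)
  grads <- list(head = list(W = outer(fw$pooled, dpred), b = dpred))
  dpooled <- as.vector(params$head$W %*% dpred)
  dx <- matrix(dpooled / L_last, L_last, length(dpooled), byrow = TRUE)
  c(grads, .encoder_bwd(params, config, geo, fw$enc, dx))
}

#' Forward pass of the U-shaped segmentation network
#'
#' Runs the encoder keeping each level's pre-merge output, decodes back to the
#' patch grid with 1-to-4 patch partition plus skip connections, maps every
#' patch token to `6 * num_classes` logits, and scatters them to the patch
#' vertices (averaging where neighbouring patches share a vertex).
#'
#' @inheritParams forward_regression
#' @param config An [mssit_config()] with `task = "segmentation"`.
#' @return `|V| x num_classes` matrix of per-vertex class logits. Apply
#'   [softmax_rows()] for probabilities.
#' @export
forward_segmentation <- function(signal, config, params, keep_attention = FALSE) {
  if (config$task != "segmentation")
    stop("`config$task` must be segmentation")
  geo <- .config_geometry(config)
  fw <- .forward_seg_full(signal, config, params, geo,
                          keep_attention = keep_attention)
  out <- fw$logits
  if (keep_attention) attr(out, "attention") <- fw$enc$attention
  out
}

# scatter map from (patch, slot) pairs to vertices; cached per geometry
.seg_scatter <- function(geo) {
  ids <- as.vector(geo$partition$patch_vertex_ids) + 1L  # column-major: slots
  counts <- tabulate(ids, nbins = geo$n_vertices)
  list(ids = ids, counts = counts)
}

.forward_seg_full <- function(signal, config, params, geo, train = FALSE,
                              keep_attention = FALSE) {
  X0 <- tokenize(signal, geo$partition)
  enc <- .encoder_fwd(params, X0, config, geo, train, keep_attention)
  nl <- config$n_levels
  x <- enc$x
  dec_cache <- vector("list", nl - 1L)
  for (i in seq_len(nl - 1L)) {
    l <- nl - i
    dp <- params$decoder[[i]]
    cat_x <- .partition_up_fwd(x, enc$skips[[l]])
    dc <- list(cat_x = cat_x, d_parent = ncol(x))
    x <- .linear_fwd(cat_x, dp$proj$W, dp$proj$b)
    if (!is.null(dp$blocks)) {
      dc$blocks <- vector("list", length(dp$blocks))
      for (bidx in seq_along(dp$blocks)) {
        dc$blocks[[bidx]]$x_in <- x
        bf <- .block_fwd(x, dp$blocks[[bidx]], geo$wmaps[[l]], config$heads[l])
        dc$blocks[[bidx]]$cache <- bf$cache
        x <- bf$y
      }
    }
    dec_cache[[i]] <- dc
  }
  token_logits <- .linear_fwd(x, params$seg_head$W, params$seg_head$b)
  # rows: patches; columns grouped as slot-major blocks of num_classes
  K <- config$num_classes
  sc <- .seg_scatter(geo)
  L0 <- nrow(token_logits)
  # (patch, slot) -> vertex, averaging shared boundary vertices
  flat <- matrix(0, 6L * L0, K)
  for (s in 1:6)
    flat[((s - 1L) * L0 + 1L):(s * L0), ] <-
      token_logits[, ((s - 1L) * K + 1L):(s * K), drop = FALSE]
  logits <- rowsum(flat, group = sc$ids, reorder = TRUE) / sc$counts
  list(logits = logits, token_logits = token_logits, dec_x = x,
       dec_cache = dec_cache, enc = enc)
}

.backward_seg_full <- function(config, geo, params, fw, dlogits) {
  K <- config$num_classes
  sc <- .seg_scatter(geo)
  dflat <- dlogits[sc$ids, , drop = FALSE] / sc$counts[sc$ids]
  L0 <- nrow(fw$token_logits)
  dtoken <- matrix(0, L0, 6L * K)
  for (s in 1:6)
    dtoken[, ((s - 1L) * K + 1L):(s * K)] <-
      dflat[((s - 1L) * L0 + 1L):(s * L0), , drop = FALSE]
  gh <- .linear_bwd(fw$dec_x, params$seg_head$W, dtoken)
  grads <- list(seg_head = list(W = gh$dW, b = gh$db))
  dx <- gh$dx
  nl <- config$n_levels
  dskips <- vector("list", nl)
  grads$decoder <- vector("list", nl - 1L)
  for (i in rev(seq_len(nl - 1L))) {
    l <- nl - i
    dp <- params$decoder[[i]]
    dc <- fw$dec_cache[[i]]
    gdec <- list()
    if (!is.null(dp$blocks)) {
      gdec$blocks <- vector("list", length(dp$blocks))
      for (bidx in rev(seq_along(dp$blocks))) {
        bb <- .block_bwd(dc$blocks[[bidx]]$cache, dp$blocks[[bidx]],
                         dc$blocks[[bidx]]$x_in, dx)
        gdec$blocks[[bidx]] <- bb$grads
        dx <- bb$dx
      }
    }
    gl <- .linear_bwd(dc$cat_x, dp$proj$W, dx)
    gdec$proj <- list(W = gl$dW, b = gl$db)
    gdec <- gdec[intersect(c("proj", "blocks"), names(gdec))]
    grads$decoder[[i]] <- gdec
    pu <- .partition_up_bwd(gl$dx, dc$d_parent)
    dskips[[l]] <- pu$dskip
    dx <- pu$dx
  }
  c(grads, .encoder_bwd(params, config, geo, fw$enc, dx, dskips))
}

#' Row-wise softmax
#' @param s Numeric matrix of logits.
#' @return Matrix of the same shape whose rows sum to 1.
#' @export
softmax_rows <- function(s) .softmax_rows(s)
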