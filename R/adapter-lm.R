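#' Transformer model configuration
#'
#' Dimensions of the tiny decoder-only reference transformer. Key/value
#' states have width `num_kv_heads * head_dim`; grouped-query attention
#' (fewer key/value heads than query heads) is supported, as in the large
#' models whose published dimensions the parameter accounting reproduces.
#'
#' @param vocab_size Total vocabulary size including special tokens.
#' @param num_layers Number of transformer layers (L >= 1).
#' @param hidden_size Residual-stream width; must equal
#'   `num_heads * head_dim`.
#' @param num_heads Number of query heads.
#' @param num_kv_heads Number of key/value heads; must divide `num_heads`.
#' @param head_dim Per-head dimension.
#' @param max_seq_len Maximum sequence length (positions for `[SOS]`, body,
#'   `[EOS]`; the trait dummy position occupies no token slot).
#' @param ff_mult Feed-forward expansion factor (default 4).
#' @param sos_id,eos_id,pad_id,unk_id 1-based ids of the special tokens.
#' @return Object of class `model_config`.
#' @export
model_config <- function(vocab_size, num_layers, hidden_size,
                         num_heads = 1L, num_kv_heads = num_heads,
                         head_dim = hidden_size %/% num_heads,
                         max_seq_len = 64L, ff_mult = 4L,
                         sos_id = 2L, eos_id = 3L, pad_id = 1L, unk_id = 4L) {
  cfg <- list(vocab_size = as.integer(vocab_size),
              num_layers = as.integer(num_layers),
              hidden_size = as.integer(hidden_size),
              num_heads = as.integer(num_heads),
              num_kv_heads = as.integer(num_kv_heads),
              head_dim = as.integer(head_dim),
              max_seq_len = as.integer(max_seq_len),
              ff_mult = as.integer(ff_mult),
              sos_id = as.integer(sos_id), eos_id = as.integer(eos_id),
              pad_id = as.integer(pad_id), unk_id = as.integer(unk_id))
  if (cfg$num_layers < 1L) stop("num_layers must be >= 1", call. = FALSE)
  if (cfg$hidden_size != cfg$num_heads * cfg$head_dim) {
    stop("hidden_size must equal num_heads * head_dim", call. = FALSE)
  }
  if (cfg$num_heads %% cfg$num_kv_heads != 0L) {
    stop("num_kv_heads must divide num_heads", call. = FALSE)
  }
  if (cfg$vocab_size < 5L) stop("vocab_size too small", call. = FALSE)
  structure(cfg, class = "model_config")
}

# width of a layer's key/value states
.kv_width <- function(model_cfg) model_cfg$num_kv_heads * model_cfg$head_dim

#' Adapter configuration
#'
#' The adapter maps a trait vector of `latent_size` continuous scores into
#' each injected layer's key/value width via learned projection matrices.
#' With `include_bias = TRUE` (default) the trait vector is augmented with a
#' constant 1, so each matrix has `latent_size + 1` rows.
#'
#' @param latent_size Number of trait dimensions t (>= 1).
#' @param include_bias Augment the trait vector with a constant 1
#'   (default `TRUE`).
#' @param inject_layers `NULL` for all layers (default), or an integer vector
#'   of 1-based layer indices; `integer(0)` disables injection entirely
#'   (an unconditioned model of matched architecture).
#' @return Object of class `adapter_config`.
#' @export
adapter_config <- function(latent_size, include_bias = TRUE,
                           inject_layers = NULL) {
  latent_size <- as.integer(latent_size)
  if (is.na(latent_size) || latent_size < 0L) {
    stop("latent_size must be a non-negative integer", call. = FALSE)
  }
  if (!is.null(inject_layers)) inject_layers <- as.integer(inject_layers)
  structure(list(latent_size = latent_size,
                 include_bias = isTRUE(include_bias),
                 inject_layers = inject_layers),
            class = "adapter_config")
}

# resolve the injected layer set against a model config
.injected_layers <- function(model_cfg, adapter_cfg) {
  if (is.null(adapter_cfg$inject_layers)) return(seq_len(model_cfg$num_layers))
  ls <- adapter_cfg$inject_layers
  if (length(ls) > 0 &&
      (any(ls < 1L) || any(ls > model_cfg$num_layers))) {
    stop("inject_layers out of range for this model", call. = FALSE)
  }
  ls
}

# effective projection input width (t, or t + 1 with the bias row)
.proj_in_width <- function(adapter_cfg) {
  adapter_cfg$latent_size + as.integer(adapter_cfg$include_bias)
}

#' Count the parameters added by the adapter
#'
#' One key and one value projection matrix per injected layer, each of shape
#' `(latent_size + include_bias) x (num_kv_heads * head_dim)`:
#' \deqn{2 \cdot |layers| \cdot (t + 1) \cdot kv\_width.}
#' With trait dimension 5 and bias this reproduces the published counts for
#' the three large decoder models the mechanism was demonstrated on:
#' 55,296 (18 layers, kv width 256), 552,960 (36 layers, kv width 1280) and
#' 393,216 (32 layers, kv width 1024).
#'
#' @param model_cfg A [model_config()].
#' @param adapter_cfg An [adapter_config()].
#' @return Integer parameter count.
#' @examples
#' gemma_like <- model_config(vocab_size = 256000, num_layers = 18,
#'                            hidden_size = 2048, num_heads = 8,
#'                            num_kv_heads = 1, head_dim = 256)
#' count_adapter_params(gemma_like, adapter_config(5))
#' @export
count_adapter_params <- function(model_cfg, adapter_cfg) {
  stopifnot(inherits(model_cfg, "model_config"),
            inherits(adapter_cfg, "adapter_config"))
  layers <- .injected_layers(model_cfg, adapter_cfg)
  2L * length(layers) * .proj_in_width(adapter_cfg) * .kv_width(model_cfg)
}

#' Initialize a set of adapter projection matrices
#'
#' One key and one value matrix per injected layer, entries i.i.d. normal
#' with SD `init_scale` (`init_scale = 0` gives exactly-zero matrices, the
#' neutral initialization that leaves the base model's behavior untouched).
#' Deterministic for a fixed seed.
#'
#' @param model_cfg A [model_config()].
#' @param adapter_cfg An [adapter_config()].
#' @param init_scale SD of the normal initializer (default 0: neutral).
#' @param seed Integer seed.
#' @return Named list (by layer index) of lists with `key` and `value`
#'   matrices, class `projection_set`.
#' @export
make_projection_set <- function(model_cfg, adapter_cfg, init_scale = 0,
                                seed = 1) {
  stopifnot(inherits(model_cfg, "model_config"),
            inherits(adapter_cfg, "adapter_config"))
  layers <- .injected_layers(model_cfg, adapter_cfg)
  nin <- .proj_in_width(adapter_cfg)
  kvw <- .kv_width(model_cfg)
  proj <- .with_seed(seed, {
    out <- list()
    for (l in layers) {
      out[[as.character(l)]] <- list(
        key = matrix(stats::rnorm(nin * kvw, sd = init_scale), nin, kvw),
        value = matrix(stats::rnorm(nin * kvw, sd = init_scale), nin, kvw))
    }
    out
  })
  structure(proj, class = "projection_set")
}

# trait vector as a 1 x (t [+1]) row, bias appended when configured
.augment_profile <- function(scores, adapter_cfg) {
  scores <- as.numeric(scores)
  if (length(scores) != adapter_cfg$latent_size) {
    stop(sprintf("profile length %d does not match adapter latent_size %d",
                 length(scores), adapter_cfg$latent_size), call. = FALSE)
  }
  if (adapter_cfg$include_bias) scores <- c(scores, 1)
  matrix(scores, nrow = 1)
}

#' Project a trait profile into one layer's key/value states
#'
#' Computes the dummy position's key and value states at an injected layer:
#' `key = p W_l^key`, `value = p W_l^value`, where `p` is the trait vector
#' augmented with a constant 1 when the adapter uses a bias row. The map is
#' linear in the profile (affine with bias).
#'
#' @param profile A [trait_profile()] or bare numeric score vector.
#' @param projections A [make_projection_set()] result.
#' @param layer_index 1-based index of an injected layer.
#' @param adapter_cfg The [adapter_config()] the projections were built with.
#' @return List with numeric vectors `key` and `value` of kv width.
#' @export
inject_trait_state <- function(profile, projections, layer_index,
                               adapter_cfg) {
  stopifnot(inherits(adapter_cfg, "adapter_config"))
  scores <- if (inherits(profile, "trait_profile")) profile$scores else profile
  pl <- projections[[as.character(layer_index)]]
  if (is.null(pl)) {
    stop("layer ", layer_index, " is not an injected layer", call. = FALSE)
  }
  p <- .augment_profile(scores, adapter_cfg)
  list(key = as.numeric(p %*% pl$key),
       value = as.numeric(p %*% pl$value))
}
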