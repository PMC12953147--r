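.checkpoint_format <- 1L

#' Save a trained checkpoint to a directory
#'
#' Writes a plain-text (JSON) checkpoint: a versioned manifest, the model
#' and adapter configurations, the tokenizer vocabulary, all weights
#' (base transformer + adapter projections), the training log, and the
#' score-standardization constants when present.
#'
#' @param checkpoint An `lm_checkpoint` from [train_adapter()].
#' @param dir Target directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
save_checkpoint <- function(checkpoint, dir) {
  stopifnot(inherits(checkpoint, "lm_checkpoint"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  model <- checkpoint$model
  wj <- function(x, f) {
    jsonlite::write_json(x, file.path(dir, f), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  wj(list(format_version = .checkpoint_format,
          files = c("config.json", "vocab.json", "weights.json",
                    "training.json")),
     "manifest.json")
  wj(list(model_cfg = unclass(model$model_cfg),
          adapter_cfg = unclass(model$adapter_cfg)),
     "config.json")
  wj(model$vocab, "vocab.json")
  wj(list(params = model$params,
          projections = unclass(model$projections)),
     "weights.json")
  wj(list(train_cfg = unclass(checkpoint$train_cfg),
          epoch_loss = checkpoint$epoch_loss,
          std_constants = checkpoint$std_constants),
     "training.json")
  invisible(dir)
}

# rebuild numeric matrices that jsonlite may have simplified
.as_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  matrix(as.numeric(x), nrow = 1)
}

#' Load a checkpoint saved with [save_checkpoint()]
#'
#' @param dir Checkpoint directory.
#' @return An `lm_checkpoint`.
#' @export
load_checkpoint <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) {
    stop("not a checkpoint directory (missing manifest.json): ", dir,
         call. = FALSE)
  }
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(as.integer(mf$format_version), .checkpoint_format)) {
    stop("unsupported checkpoint format version: ", mf$format_version,
         call. = FALSE)
  }
  rj <- function(f) {
    jsonlite::read_json(file.path(dir, f), simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  }
  cfgs <- rj("config.json")
  mcl <- cfgs$model_cfg
  mcfg <- model_config(mcl$vocab_size, mcl$num_layers, mcl$hidden_size,
                       mcl$num_heads, mcl$num_kv_heads, mcl$head_dim,
                       mcl$max_seq_len, mcl$ff_mult,
                       mcl$sos_id, mcl$eos_id, mcl$pad_id, mcl$unk_id)
  acl <- cfgs$adapter_cfg
  acfg <- adapter_config(acl$latent_size, acl$include_bias,
                         acl$inject_layers)
  vocab <- as.character(rj("vocab.json"))
  w <- rj("weights.json")
  params <- w$params
  params$tok_emb <- .as_matrix(params$tok_emb)
  params$pos_emb <- .as_matrix(params$pos_emb)
  params$out_proj <- .as_matrix(params$out_proj)
  params$layers <- lapply(params$layers, function(ly) {
    for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2")) {
      ly[[nm]] <- .as_matrix(ly[[nm]])
    }
    ly$g_attn <- as.numeric(ly$g_attn)
    ly$g_mlp <- as.numeric(ly$g_mlp)
    ly
  })
  params$g_final <- as.numeric(params$g_final)
  projections <- lapply(w$projections, function(pl) {
    list(key = .as_matrix(pl$key), value = .as_matrix(pl$value))
  })
  model <- structure(list(model_cfg = mcfg, adapter_cfg = acfg,
                          vocab = vocab, params = params,
                          projections = structure(projections,
                                                  class = "projection_set")),
                     class = "adapter_lm")
  tr <- rj("training.json")
  std <- tr$std_constants
  if (!is.null(std)) {
    std <- list(mean = unlist(std$mean), sd = unlist(std$sd))
  }
  structure(list(model = model,
                 train_cfg = structure(tr$train_cfg, class = "train_config"),
                 epoch_loss = as.numeric(tr$epoch_loss),
                 std_constants = std),
            class = "lm_checkpoint")
}
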