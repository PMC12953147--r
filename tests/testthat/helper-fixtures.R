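# shared builders for the test suite; everything is generated in code

# tiny transformer used by mechanics tests (fast, full feature coverage:
# 2 layers, grouped-query attention with 2 query heads sharing 1 kv head)
tiny_model <- function(t_dim = 2, seed = 3, adapter_init_scale = 0.05,
                       inject_layers = NULL) {
  mcfg <- model_config(vocab_size = 9, num_layers = 2, hidden_size = 8,
                       num_heads = 2, num_kv_heads = 1, head_dim = 4,
                       max_seq_len = 12)
  acfg <- adapter_config(t_dim, inject_layers = inject_layers)
  adapter_lm(mcfg, acfg, build_vocab(letters[1:5]), seed = seed,
             adapter_init_scale = adapter_init_scale)
}

# small synthetic configuration for quick corpus-level tests
small_synth <- function(...) {
  defaults <- list(t = 2, vocab_size = 40, markers_per_trait = 3,
                   n_participants = 30, messages_per_participant = 4,
                   message_length_range = c(5L, 8L), seed = 11)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# all permutations of 1..n (independent enumeration oracle, n <= 7)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_permutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# degrees of 22.5 in radians, used by frozen circumplex values
deg <- function(x) x * pi / 180
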