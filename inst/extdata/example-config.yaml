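# Annotated run configuration for the traitlm CLI. Every field is optional;
# values shown are the defaults used when the field is omitted. CLI flags
# override config fields, and all randomness flows from --seed.

synthetic:                  # corpus simulator (simulate / evaluate)
  t: 2                      # trait dimensions
  vocab_size: 60            # base vocabulary (words w001..wNNN)
  markers_per_trait: 5      # marker tokens per trait pole
  beta: 1.0                 # log-odds slope per SD on marker tokens
  message_length_range: [8, 16]   # uniform message length, inclusive
  n_participants: 200
  messages_per_participant: 10

estimator:                  # participant-level linear trait estimator
  lambda: 0.001             # ridge penalty (0 = least squares / min-norm)

model:                      # tiny reference transformer
  num_layers: 2
  hidden_size: 32
  num_heads: 2
  num_kv_heads: 2           # fewer than num_heads enables grouped-query attention
  head_dim: 16              # hidden_size must equal num_heads * head_dim
  max_seq_len: 64

adapter:
  latent_size: 2            # trait dimensions seen by the adapter
  include_bias: true        # augment the trait vector with a constant 1
  # inject_layers: [1, 2]   # default: all layers; [] trains unconditioned

train:
  epochs: 6
  batch_size: 16
  learning_rate: 0.003
  freeze_base: false        # true updates only the adapter projections

generation:
  method: top_k             # greedy | temperature | top_k | nucleus
  temperature: 1.0
  k: 40
  p: 0.9
  max_new_tokens: 16

evaluation:
  levels: [-3, 0, 3]        # use [-3, -1.5, 0, 1.5, 3] for five levels
  samples_per_group: 5
  n_trials: 10
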