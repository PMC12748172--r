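# Small in-memory fixtures built from the synthetic generator.

make_toy_dataset <- function(n, seed = 1, size = 32L, modality = "octa") {
  lapply(seq_len(n), function(i) {
    s <- generate_sample(synth_config(modality, size = c(size, size),
                                      seed = seed + i))
    list(image = s$image, mask = s$mask, caption = s$label$caption,
         image_id = s$label$image_id)
  })
}

# CPU-friendly model profile used throughout the unit tests
toy_model_config <- function(...) {
  model_config(..., base_channels = 4L, depth = 2L, vit_dim = 16L,
               vit_heads = 2L, vit_levels = 2L, input_size = c(32L, 32L))
}

# closed-form SE parameter count for a given placement
se_param_count <- function(cfg) {
  per_stage <- function(ch) {
    hidden <- max(1, ch %/% cfg$se_reduction)
    2 * ch * hidden
  }
  chans <- cfg$base_channels * 2^(seq_len(cfg$depth) - 1)
  n_sides <- switch(cfg$se_placement, none = 0, down = 1, up = 1, all = 2)
  n_sides * sum(vapply(chans, per_stage, numeric(1)))
}

# closed-form gate parameter count of the transformer branch
gate_param_count <- function(cfg) {
  if (!cfg$gating_enabled) return(0L)
  n_layers <- cfg$vit_levels * cfg$vit_depth +
    (cfg$vit_levels - 1L) * cfg$vit_depth
  g <- cfg$gate_granularity
  n_layers * 2L * (cfg$vit_dim * g + g)
}
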