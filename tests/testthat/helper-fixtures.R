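# Small fixtures shared across tests: a 32x32 configuration with a narrow
# network keeps single forward/backward passes in the tens of milliseconds.

tiny_cfg <- function(...) {
  ctg_config(desk_profile = TRUE, image_size = 32L,
             backbone = list(base = 2L, channels = 8L),
             cls = list(d1 = 4L), ...)
}

tiny_phantom_cfg <- function(seed = 3, ...) {
  phantom_config(image_height = 32, image_width = 32,
                 lesion_radius_range = c(3, 5), seed = seed, ...)
}

tiny_phantoms <- function(n = 4, seed = 3, ...) {
  generate_dataset(tiny_phantom_cfg(seed = seed, ...), n)
}

# shared_features built directly from an array, bypassing the encoder;
# used to probe the task units with controlled inputs
as_shared_features <- function(values, image_size, stride = 8L) {
  structure(list(values = values, stride = stride, image_size = image_size),
            class = "shared_features")
}

as_coarse_probs <- function(values, image_size) {
  structure(list(values = values, image_size = image_size),
            class = "coarse_mask_probs")
}

as_class_prediction <- function(g_global, h_score,
                                logits = log(pmax(h_score, 1e-12))) {
  structure(list(g_global = g_global, h_score = h_score, logits = logits),
            class = "class_prediction")
}
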