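# Parameter and multiply-accumulate accounting.
#
# Parameter counts are exact (lengths of trainable leaves). MAC counts are
# collected by the tape's matrix-product and convolution ops during a
# single-image forward pass; GFLOPs are reported as 2 * MACs (stated
# convention).

#' Count MACs of an arbitrary forward computation
#'
#' Runs `fn()` with the multiply-accumulate counter enabled and returns its
#' value together with the MACs of every matrix product and convolution
#' executed.
#'
#' @param fn a zero-argument function
#' @return list with `value` and `macs`
#' @export
profile_forward <- function(fn) {
  ag_profile_start()
  value <- tryCatch(fn(), error = function(e) {
    ag_profile_stop()
    stop(e)
  })
  list(value = value, macs = ag_profile_stop())
}

#' Profile a detector
#'
#' @param model a [build_model()] detector
#' @param input_size square input side (default: the configured image size)
#' @return list with `params`, `macs`, `params_m` (10^6), `gflops`
#'   (2 * MACs / 10^9)
#' @export
profile_model <- function(model, input_size = NULL) {
  if (is.null(input_size)) input_size <- model$config$image_size
  x <- array(0.5, c(input_size, input_size, 1L, 3L))
  pr <- profile_forward(function() {
    ag_no_grad(nn_model_forward(model, x, training = FALSE))
  })
  params <- sum(vapply(model$params, function(p) length(p$v), 0))
  list(params = params, macs = pr$macs,
       params_m = params / 1e6, gflops = 2 * pr$macs / 1e9)
}

#' Profile every variant of the ablation grid
#'
#' Builds all 2^3 combinations of (backbone, intra-scale, aggregation) at a
#' shared width/depth configuration and tabulates parameters and MACs.
#'
#' @param hidden_dim,num_heads,num_queries,decoder_layers,num_classes,
#'   image_size,widths,depths,n_ret,repc3_depth passed to [model_config()]
#' @param seed initialisation seed
#' @return data frame with one row per variant
#' @export
profile_grid <- function(hidden_dim = 32L, num_heads = 4L, num_queries = 30L,
                         decoder_layers = 2L, num_classes = 4L,
                         image_size = 96L, widths = c(16L, 32L, 48L, 64L),
                         depths = c(1L, 1L, 2L, 1L), n_ret = 1L,
                         repc3_depth = 3L, seed = 0L) {
  grid <- expand.grid(backbone = c("resnet18", "cspmambaout"),
                      intra_scale = c("aifi_mhsa", "aifi_mala"),
                      aggregation = c("repc3", "retblockc3"),
                      stringsAsFactors = FALSE)
  out <- grid
  out$params <- NA_real_
  out$macs <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- model_config(backbone = grid$backbone[i],
                        intra_scale = grid$intra_scale[i],
                        aggregation = grid$aggregation[i],
                        hidden_dim = hidden_dim, num_heads = num_heads,
                        num_queries = num_queries,
                        decoder_layers = decoder_layers,
                        num_classes = num_classes, image_size = image_size,
                        seed = seed, widths = widths, depths = depths,
                        n_ret = n_ret, repc3_depth = repc3_depth)
    m <- build_model(cfg)
    pr <- profile_model(m, image_size)
    out$params[i] <- pr$params
    out$macs[i] <- pr$macs
  }
  out
}
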