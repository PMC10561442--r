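#' Assemble the full dual-path segmentation network
#'
#' Wires the VGG16-style encoder into the spatial path (boundary refinement
#' over blocks 1-2), the context path (multi-scale context extraction and
#' feature selection over blocks 3-5), the dual-path fusion block, and a
#' prediction head (1x1 convolution to one channel, sigmoid, upsample to the
#' input resolution). Blocks listed in `config$modules` are active; the
#' others are replaced by identity/bypass paths so that ablation rows are
#' structurally comparable.
#'
#' Weights are drawn from a seeded Gaussian (`config$seed`, `config$init`);
#' the forward pass is deterministic given fixed parameters.
#'
#' @param config An [modelConfig()] object.
#' @return An object of class `adffnet` with elements `config`, the layer
#'   structure, and `params` (named list of parameter nodes).
#' @examples
#' model <- assembleADFFNet(modelConfig(input_size = 64, base_channels = 8))
#' nParams(model)
#' @export
assembleADFFNet <- function(config) {
  stopifnot(inherits(config, "adffnet_config"))
  enc <- buildEncoder(config)        # seeds the RNG with config$seed
  b <- config$base_channels
  ch <- enc$channels                 # b, 2b, 4b, 8b, 8b
  layers <- list(
    encoder = enc,
    br = brModule(ch[2], config$br_kernel, config$init),
    mcie = list(mcieModule(ch[3], config$dilation_rates, config$init),
                mcieModule(ch[4], config$dilation_rates, config$init),
                mcieModule(ch[5], config$dilation_rates, config$init)),
    fs = fsModule(ch[3:5], config$fs_reduction, config$init),
    dff = dffModule(ch[3], b, config$init),
    head = newConv(1L, 1L, b, 1L, config$init))
  params <- c(collectParams(enc$blocks, "enc"),
              collectParams(layers$br, "br"),
              collectParams(layers$mcie, "mcie"),
              collectParams(layers$fs, "fs"),
              collectParams(layers$dff, "dff"),
              collectParams(layers$head, "head"))
  structure(list(config = config, layers = layers, params = params),
            class = "adffnet")
}

#' Number of trainable parameters
#' @param model An `adffnet` model or `adffnet_encoder`.
#' @return Integer parameter count.
#' @export
nParams <- function(model) {
  params <- if (inherits(model, "adffnet")) {
    model$params
  } else if (inherits(model, "adffnet_encoder")) {
    collectParams(model$blocks, "enc")
  } else {
    stop("expected an adffnet or adffnet_encoder object", call. = FALSE)
  }
  sum(vapply(params, function(p) length(p$val), numeric(1)))
}

#' @export
print.adffnet <- function(x, ...) {
  cat("ADFFNet segmentation model\n")
  print(x$config)
  cat("  trainable parameters:", format(nParams(x), big.mark = ","), "\n")
  invisible(x)
}

# Full tape forward; x an agNode (H, W, 3, N). Returns list of nodes; `p` is
# the probability mask at input resolution.
modelForwardNode <- function(model, x, training = FALSE) {
  cfg <- model$config
  on <- function(m) m %in% cfg$modules
  d <- dim(x$val)
  cs <- encForwardNode(model$layers$encoder, x)
  # spatial path
  if (on("BR")) {
    brOut <- brForward(model$layers$br, cs$c1, cs$c2)
    l <- brOut$x
  } else {
    l <- cs$c1
  }
  # context path
  us <- lapply(1:3, function(m) {
    if (on("MCIE")) mcieForward(model$layers$mcie[[m]], cs[[m + 2L]])
    else cs[[m + 2L]]
  })
  fsOut <- fsForwardNode(model$layers$fs, us[[1]], us[[2]], us[[3]],
                         select = on("FS"))
  # fusion + head
  dffOut <- dffForwardNode(model$layers$dff, fsOut$v, l,
                           training = training, fuse = on("DFF"))
  logit <- convFwd(model$layers$head, dffOut$m)
  prob <- agSigmoid(logit)
  p <- if (cfg$head_upsample == "bilinear") {
    agResizeBilinear(prob, d[1], d[2])
  } else {
    agResizeNearest(prob, d[1], d[2])
  }
  list(p = p, m = dffOut$m, v = fsOut$v, l = l,
       alpha = fsOut$alpha, beta = fsOut$beta, gamma = fsOut$gamma,
       dff_attention = dffOut$attention)
}

#' Forward pass of the assembled model
#'
#' @param model An `adffnet` model.
#' @param x Image array `(H, W, 3)` or `(H, W, 3, N)` with values in
#'   \[0, 1\] and H, W divisible by 32.
#' @return Probability mask array (same spatial size as the input, one
#'   channel); entries lie strictly in (0, 1).
#' @export
adffnetPredict <- function(model, x) {
  was3d <- length(dim(x)) == 3L
  out <- modelForwardNode(model, agConst(ensure4d(x)), training = FALSE)
  p <- out$p$val
  if (was3d) dropTo3d(p) else p
}

# ---- checkpointing ----

#' Save / load a model checkpoint
#'
#' The checkpoint stores the configuration, every parameter array, and the
#' batch-normalisation running statistics, so a reloaded model reproduces
#' the saved model's forward pass bitwise.
#'
#' @param model An `adffnet` model.
#' @param path File path (RDS).
#' @return `saveModel` returns `path` invisibly; `loadModel` returns the
#'   reconstructed model.
#' @export
saveModel <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  state <- lapply(model$params, function(p) p$val)
  bn <- model$layers$dff$bn$state
  obj <- list(config = unclass(model$config), params = state,
              bn_running = list(mean = bn$running_mean, var = bn$running_var),
              package_version = as.character(utils::packageVersion("adffnet")))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(modelConfig, obj$config)
  model <- assembleADFFNet(cfg)
  if (!setequal(names(model$params), names(obj$params))) {
    miss <- c(setdiff(names(model$params), names(obj$params)),
              setdiff(names(obj$params), names(model$params)))
    stop("checkpoint/config mismatch in parameter field(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  for (nm in names(obj$params)) {
    cur <- model$params[[nm]]$val
    new <- obj$params[[nm]]
    if (!identical(dim(cur), dim(new)) || length(cur) != length(new)) {
      stop("checkpoint/config mismatch: parameter ", nm,
           " has incompatible shape", call. = FALSE)
    }
    model$params[[nm]]$val <- new
  }
  model$layers$dff$bn$state$running_mean <- obj$bn_running$mean
  model$layers$dff$bn$state$running_var <- obj$bn_running$var
  model
}
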