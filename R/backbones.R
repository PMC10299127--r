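# Shape-relevant layer sequences of the supported convolutional backbones.
# Each entry lists every layer that changes the spatial side (kernel,
# stride, padding), in order, following the Keras reference architectures;
# stride-1 'same' layers are omitted because they are shape-neutral.
# 'valid': side -> floor((side - k)/stride) + 1 ; 'same': side -> ceil(side/stride).
backbone_registry <- function() {
  vgg <- list(list(2, 2, "valid"), list(2, 2, "valid"), list(2, 2, "valid"),
              list(2, 2, "valid"), list(2, 2, "valid"))       # 5 max-pools
  resnet <- list(list(7, 2, "same"),   # conv1 (zero-padded 7x7/2)
                 list(3, 2, "same"),   # stem max-pool
                 list(1, 2, "same"), list(1, 2, "same"), list(1, 2, "same"))
  inception <- list(list(3, 2, "valid"), list(3, 1, "valid"),
                    list(3, 2, "valid"),                       # stem pool 1
                    list(3, 1, "valid"),
                    list(3, 2, "valid"),                       # stem pool 2
                    list(3, 2, "valid"),                       # grid reduction A
                    list(3, 2, "valid"))                       # grid reduction B
  xception <- list(list(3, 2, "valid"), list(3, 1, "valid"),
                   list(3, 2, "same"), list(3, 2, "same"), list(3, 2, "same"),
                   list(3, 2, "same"))                         # exit-flow pool
  tiny <- list(list(2, 2, "valid"), list(2, 2, "valid"), list(2, 2, "valid"))
  list(
    ResNet152V2       = list(layers = resnet,    min_input_side = 32L,
                             n_features = 2048L, preprocess = "tf"),
    InceptionV3       = list(layers = inception, min_input_side = 75L,
                             n_features = 2048L, preprocess = "tf"),
    ResNet50          = list(layers = resnet,    min_input_side = 32L,
                             n_features = 2048L, preprocess = "caffe"),
    InceptionResNetV2 = list(layers = inception, min_input_side = 75L,
                             n_features = 1536L, preprocess = "tf"),
    Xception          = list(layers = xception,  min_input_side = 71L,
                             n_features = 2048L, preprocess = "tf"),
    VGG19             = list(layers = vgg,       min_input_side = 32L,
                             n_features = 512L,  preprocess = "caffe"),
    VGG16             = list(layers = vgg,       min_input_side = 32L,
                             n_features = 512L,  preprocess = "caffe"),
    TinyConv          = list(layers = tiny,      min_input_side = 8L,
                             n_features = 32L,   preprocess = "tf")
  )
}

#' Registered backbone names
#'
#' The seven standard ImageNet architectures plus the package's small
#' trainable surrogate, `TinyConv`.
#'
#' @return Character vector of backbone names.
#' @export
list_backbones <- function() names(backbone_registry())

#' Backbone specification
#'
#' @param name One of [list_backbones()].
#' @param weights `"random"` or `"imagenet"`. `TinyConv` never claims
#'   ImageNet weights. Pretrained ImageNet weights are not shipped with
#'   this package and requesting them raises an error at
#'   instantiation/extraction time.
#' @param frozen Should the backbone stay frozen during phase-1 training?
#' @return Object of class `backbone_spec`.
#' @export
backbone_spec <- function(name, weights = c("random", "imagenet"),
                          frozen = TRUE) {
  reg <- backbone_registry()
  if (!name %in% names(reg))
    stopf("unknown backbone '%s' (registered: %s)", name,
          paste(names(reg), collapse = ", "))
  weights <- match.arg(weights)
  if (name == "TinyConv" && weights == "imagenet")
    stopf("TinyConv has no ImageNet weights")
  structure(c(list(name = name, weights = weights, frozen = frozen),
              reg[[name]]),
            class = "backbone_spec")
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat(sprintf("<backbone_spec> %s (weights=%s, frozen=%s, min input %d)\n",
              x$name, x$weights, x$frozen, x$min_input_side))
  invisible(x)
}

#' Feature-map spatial side of a backbone
#'
#' Propagates a square input of side `input_side` through the backbone's
#' convolutional stage (truncated before any fully connected layer) and
#' returns the spatial side of the final feature map. This is exact
#' architecture arithmetic: `valid` layers map side to
#' `floor((side - k)/stride) + 1`, `same` layers to `ceil(side/stride)`.
#'
#' @param backbone Backbone name or [backbone_spec()].
#' @param input_side Input spatial side (>= the backbone's minimum).
#' @return Integer spatial side length.
#' @examples
#' feature_map_side("VGG16", 116)      # 3
#' feature_map_side("InceptionV3", 116) # 2
#' @export
feature_map_side <- function(backbone, input_side) {
  spec <- if (inherits(backbone, "backbone_spec")) backbone
          else backbone_spec(backbone)
  if (!is_count(input_side)) stopf("input_side must be a positive integer")
  if (input_side < spec$min_input_side)
    stopf("%s requires input side >= %d, got %d",
          spec$name, spec$min_input_side, input_side)
  side <- as.integer(input_side)
  for (ly in spec$layers) {
    k <- ly[[1]]; s <- ly[[2]]; pad <- ly[[3]]
    side <- if (pad == "valid") (side - k) %/% s + 1L else ceiling(side / s)
    if (side < 1L)
      stopf("input side %d collapses to nothing inside %s", input_side, spec$name)
  }
  as.integer(side)
}

#' Feature-map shape of a backbone
#'
#' @inheritParams feature_map_side
#' @return Integer vector `(side, side, n_features)`.
#' @export
feature_map_shape <- function(backbone, input_side) {
  spec <- if (inherits(backbone, "backbone_spec")) backbone
          else backbone_spec(backbone)
  s <- feature_map_side(spec, input_side)
  c(s, s, spec$n_features)
}
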