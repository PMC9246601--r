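# Architecture representation: typed, parameterized layer sequences in the
# "C2D | BN | ..." pipe notation, structural constraints and minimal-edit
# repair. A network is always a plain sequence; no branching topologies.

#' Layer vocabulary
#'
#' The seven layer abbreviations the search operates over:
#' `C2D` (2-D convolution), `BN` (batch normalization), `DO` (dropout),
#' `MP` (max pooling), `AP` (average pooling), `DE` (dense / fully
#' connected), `F` (flatten).
#'
#' @export
LAYER_KINDS <- c("C2D", "BN", "DO", "MP", "AP", "DE", "F")

# parameter names each kind accepts (and requires, unless defaulted)
.LAYER_PARAMS <- list(
  C2D = c("filters", "kernel"),
  BN  = character(0),
  DO  = "rate",
  MP  = "pool",
  AP  = "pool",
  DE  = "units",
  F   = character(0)
)

#' Single layer specification
#'
#' @param kind one of [LAYER_KINDS].
#' @param ... layer parameters: `C2D` takes `filters` (filter count) and
#'   `kernel` (square kernel side, pixels); `MP`/`AP` take `pool` (square
#'   pool side, pixels); `DE` takes `units`; `DO` takes `rate` in (0,1);
#'   `BN` and `F` take none.
#' @return a `layer_spec` object.
#' @examples
#' layer_spec("C2D", filters = 32, kernel = 3)
#' layer_spec("BN")
#' @export
layer_spec <- function(kind, ...) {
  kind <- toupper(as.character(kind))
  if (length(kind) != 1L || !kind %in% LAYER_KINDS) {
    stop(sprintf("unknown layer kind '%s'", kind))
  }
  params <- list(...)
  allowed <- .LAYER_PARAMS[[kind]]
  extra <- setdiff(names(params), allowed)
  if (length(extra)) {
    stop(sprintf("layer %s does not take parameter(s): %s", kind,
                 paste(extra, collapse = ", ")))
  }
  missing <- setdiff(allowed, names(params))
  if (length(missing)) {
    stop(sprintf("layer %s requires parameter(s): %s", kind,
                 paste(missing, collapse = ", ")))
  }
  for (p in c("filters", "kernel", "pool", "units")) {
    if (p %in% names(params)) {
      v <- params[[p]]
      if (!is.numeric(v) || length(v) != 1L || v < 1 || v != floor(v)) {
        stop(sprintf("layer %s: %s must be a whole number >= 1", kind, p))
      }
      params[[p]] <- as.integer(v)
    }
  }
  if ("rate" %in% names(params)) {
    r <- params$rate
    if (!is.numeric(r) || length(r) != 1L || r <= 0 || r >= 1) {
      stop("dropout rate must lie strictly in (0, 1)")
    }
  }
  structure(list(kind = kind, params = params), class = "layer_spec")
}

#' @export
format.layer_spec <- function(x, ...) x$kind

#' @export
print.layer_spec <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste0("(", paste(names(x$params), unlist(x$params), sep = "=",
                      collapse = ", "), ")")
  } else ""
  cat(x$kind, ps, "\n", sep = "")
  invisible(x)
}

#' Architecture: an ordered layer sequence plus input shape
#'
#' @param layers list of [layer_spec()] objects.
#' @param input_shape integer vector `(height, width, channels)` in pixels
#'   and channels.
#' @return an `architecture` object.
#' @export
architecture <- function(layers, input_shape = c(64L, 64L, 3L)) {
  if (!is.list(layers) || length(layers) < 1L) {
    stop("an architecture needs at least one layer")
  }
  ok <- vapply(layers, inherits, logical(1), what = "layer_spec")
  if (!all(ok)) stop("all layers must be layer_spec objects")
  kinds <- vapply(layers, `[[`, character(1), "kind")
  if (sum(kinds == "F") > 1L) stop("an architecture may contain at most one F layer")
  if (length(input_shape) != 3L || any(input_shape < 1)) {
    stop("input_shape must be (height, width, channels), all >= 1")
  }
  structure(list(layers = layers, input_shape = as.integer(input_shape)),
            class = "architecture")
}

arch_kinds <- function(arch) vapply(arch$layers, `[[`, character(1), "kind")

#' @export
length.architecture <- function(x) length(x$layers)

#' @export
print.architecture <- function(x, ...) {
  cat("<architecture> ", format_architecture(x),
      sprintf("  [input %dx%dx%d]\n", x$input_shape[1], x$input_shape[2],
              x$input_shape[3]), sep = "")
  invisible(x)
}

#' Default layer parameters used when parsing bare layer tokens
#'
#' @return named list of per-kind default parameter lists.
#' @export
layer_defaults <- function() {
  list(
    C2D = list(filters = 32L, kernel = 3L),
    MP  = list(pool = 2L),
    AP  = list(pool = 2L),
    DE  = list(units = 64L),
    DO  = list(rate = 0.5),
    BN  = list(),
    F   = list()
  )
}

#' Parse the pipe-delimited layer notation
#'
#' Parses strings such as `"C2D | BN | MP | F | DE"` into an
#' [architecture()]. Tokens are case-insensitive; unspecified layer
#' parameters are filled from `defaults`.
#'
#' @param text a single string of layer abbreviations separated by `|`.
#' @param defaults per-kind parameter defaults, see [layer_defaults()].
#' @param input_shape passed to [architecture()].
#' @return an `architecture`.
#' @examples
#' parse_architecture("C2D | BN | MP | F | DE")
#' @export
parse_architecture <- function(text, defaults = layer_defaults(),
                               input_shape = c(64L, 64L, 3L)) {
  if (!is.character(text) || length(text) != 1L) {
    stop("text must be a single string")
  }
  tokens <- strsplit(text, "|", fixed = TRUE)[[1]]
  tokens <- toupper(trimws(tokens))
  if (length(tokens) == 0L || all(tokens == "")) stop("empty architecture string")
  layers <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (!tok %in% LAYER_KINDS) {
      stop(sprintf("unknown layer token '%s' at position %d", tok, i))
    }
    layers[[i]] <- do.call(layer_spec, c(list(kind = tok), defaults[[tok]]))
  }
  architecture(layers, input_shape = input_shape)
}

#' Format an architecture in the pipe notation
#'
#' Inverse of [parse_architecture()] up to whitespace normalization:
#' `format_architecture(parse_architecture(s))` reproduces `s` with a single
#' `" | "` between uppercase tokens.
#'
#' @param arch an [architecture()].
#' @return a single string.
#' @export
format_architecture <- function(arch) {
  stopifnot(inherits(arch, "architecture"))
  paste(arch_kinds(arch), collapse = " | ")
}

#' Structural constraint set
#'
#' The three design rules every candidate must satisfy: at least
#' `min_dense` DE layers; a flatten (F) must occur before the first DE; no
#' convolution after the flatten.
#'
#' @param min_dense minimum number of DE layers (default 1).
#' @param flatten_before_dense require F before the first DE.
#' @param no_conv_after_flatten forbid C2D after F.
#' @return a `constraint_set` object.
#' @export
constraint_set <- function(min_dense = 1L, flatten_before_dense = TRUE,
                           no_conv_after_flatten = TRUE) {
  stopifnot(min_dense >= 0)
  structure(list(min_dense = as.integer(min_dense),
                 flatten_before_dense = isTRUE(flatten_before_dense),
                 no_conv_after_flatten = isTRUE(no_conv_after_flatten)),
            class = "constraint_set")
}

#' Validate an architecture against the structural rules
#'
#' Violations are values, not errors: an empty list means the architecture
#' is feasible.
#'
#' @param arch an [architecture()].
#' @param rules a [constraint_set()].
#' @return list of violations, each with fields `rule` and `index` (the
#'   offending layer position, `NA` when no position applies).
#' @export
validate_architecture <- function(arch, rules = constraint_set()) {
  stopifnot(inherits(arch, "architecture"), inherits(rules, "constraint_set"))
  kinds <- arch_kinds(arch)
  out <- list()
  de_idx <- which(kinds == "DE")
  f_idx <- which(kinds == "F")
  if (length(de_idx) < rules$min_dense) {
    out[[length(out) + 1L]] <- list(rule = "min_dense", index = NA_integer_)
  }
  if (rules$flatten_before_dense) {
    # target position: the first DE, or the sequence end if DE is absent
    target <- if (length(de_idx)) de_idx[1] else length(kinds) + 1L
    if (!any(f_idx < target)) {
      out[[length(out) + 1L]] <- list(rule = "flatten_before_dense",
                                      index = if (length(de_idx)) de_idx[1] else NA_integer_)
    }
  }
  if (rules$no_conv_after_flatten && length(f_idx)) {
    bad <- which(kinds == "C2D" & seq_along(kinds) > f_idx[1])
    for (b in bad) {
      out[[length(out) + 1L]] <- list(rule = "no_conv_after_flatten", index = b)
    }
  }
  out
}

#' Repair an architecture into feasibility
#'
#' Minimal-edit repair enforcing the structural rules: append a DE layer if
#' none exists, insert F immediately before the first DE if missing, and
#' drop C2D layers occurring after F. Extra F layers beyond the first are
#' dropped.
#'
#' @param arch an [architecture()].
#' @param rules a [constraint_set()].
#' @param defaults parameter defaults for inserted layers.
#' @return a feasible `architecture`.
#' @export
repair_architecture <- function(arch, rules = constraint_set(),
                                defaults = layer_defaults()) {
  stopifnot(inherits(arch, "architecture"))
  layers <- arch$layers
  kinds <- vapply(layers, `[[`, character(1), "kind")
  # keep only the earliest F
  f_all <- which(kinds == "F")
  if (length(f_all) > 1L) {
    layers <- layers[-f_all[-1]]
    kinds <- kinds[-f_all[-1]]
  }
  if (rules$min_dense > 0 && !any(kinds == "DE")) {
    layers <- c(layers, list(do.call(layer_spec,
                                     c(list(kind = "DE"), defaults$DE))))
    kinds <- c(kinds, "DE")
  }
  de1 <- which(kinds == "DE")[1]
  if (rules$flatten_before_dense && !is.na(de1) && !any(which(kinds == "F") < de1)) {
    # a lone F after the first DE is moved by delete+insert
    f_late <- which(kinds == "F")
    if (length(f_late)) {
      layers <- layers[-f_late]
      kinds <- kinds[-f_late]
      de1 <- which(kinds == "DE")[1]
    }
    layers <- append(layers, list(layer_spec("F")), after = de1 - 1L)
    kinds <- append(kinds, "F", after = de1 - 1L)
  }
  if (rules$no_conv_after_flatten) {
    f1 <- which(kinds == "F")[1]
    if (!is.na(f1)) {
      bad <- which(kinds == "C2D" & seq_along(kinds) > f1)
      if (length(bad)) {
        layers <- layers[-bad]
        kinds <- kinds[-bad]
      }
    }
  }
  architecture(layers, input_shape = arch$input_shape)
}

#' Serialize an architecture to JSON
#'
#' The descriptor holds `input_shape`, the canonical `notation` string and
#' the full `layers` list with parameters; [architecture_from_json()] is the
#' inverse.
#'
#' @param arch an [architecture()].
#' @param path optional file to write to.
#' @return JSON string (invisibly when `path` is given).
#' @export
architecture_to_json <- function(arch, path = NULL) {
  stopifnot(inherits(arch, "architecture"))
  obj <- list(
    input_shape = arch$input_shape,
    notation = format_architecture(arch),
    layers = lapply(arch$layers, function(l) c(list(kind = l$kind), l$params))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname architecture_to_json
#' @param json JSON string or path to a JSON file.
#' @export
architecture_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE,
                            simplifyVector = TRUE)
  layers <- lapply(obj$layers, function(l) {
    kind <- l$kind
    l$kind <- NULL
    do.call(layer_spec, c(list(kind = kind), l))
  })
  architecture(layers, input_shape = obj$input_shape)
}
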