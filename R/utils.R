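#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Hypoglycaemia event categories
#'
#' The three event categories the model accounts for: non-severe daytime,
#' non-severe nocturnal and severe hypoglycaemia.
#'
#' @return Character vector of category names.
#' @export
hypo_categories <- function() c("daytime", "nocturnal", "severe")

#' Patient groups covered by the model
#'
#' Three regimens are compared: type 1 diabetes on basal-bolus insulin
#' (`T1DM_BB`), type 2 diabetes on basal insulin plus oral agents
#' (`T2DM_BOT`) and type 2 diabetes on basal-bolus insulin (`T2DM_BB`).
#' `T2DM_BOT` has no bolus component.
#'
#' @return Character vector of group labels.
#' @export
patient_groups <- function() c("T1DM_BB", "T2DM_BOT", "T2DM_BB")

# relative range (max - min) / mean, used for cross-group parameter spreads
rel_range <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(0)
  (max(x) - min(x)) / mean(x)
}

rel_err <- function(modelled, published) {
  ifelse(published == 0, abs(modelled - published),
         abs(modelled - published) / abs(published))
}

stop_field <- function(path, msg) {
  stop(sprintf("invalid parameter `%s`: %s", path, msg), call. = FALSE)
}

check_number <- function(x, path, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop_field(path, "missing")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(path, "must be a single finite number")
  if (strict_lower && x <= lower)
    stop_field(path, sprintf("must be > %s", lower))
  if (!strict_lower && x < lower)
    stop_field(path, sprintf("must be >= %s", lower))
  if (x > upper)
    stop_field(path, sprintf("must be <= %s", upper))
  invisible(x)
}

check_flag <- function(x, path) {
  if (is.null(x)) stop_field(path, "missing")
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_field(path, "must be TRUE or FALSE")
  invisible(x)
}

# walk a nested list / named vector by a dot-separated path
get_param <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  node <- params
  for (k in keys) {
    if (is.list(node)) {
      if (!k %in% names(node)) return(NULL)
      node <- node[[k]]
    } else if (!is.null(names(node)) && k %in% names(node)) {
      node <- node[[k]]
    } else {
      return(NULL)
    }
  }
  node
}

set_param_ <- function(node, keys, value) {
  k <- keys[[1L]]
  if (is.list(node)) {
    if (!k %in% names(node)) stop("unknown parameter path", call. = FALSE)
  } else {
    if (is.null(names(node)) || !k %in% names(node))
      stop("unknown parameter path", call. = FALSE)
  }
  if (length(keys) == 1L) {
    node[[k]] <- value
  } else {
    node[[k]] <- set_param_(node[[k]], keys[-1L], value)
  }
  node
}

set_param <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  out <- tryCatch(set_param_(params, keys, value),
                  error = function(e) stop(sprintf("unknown parameter path `%s`", path),
                                           call. = FALSE))
  out
}
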