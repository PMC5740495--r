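# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows distinct across n pull rename relocate
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats pchisq pnorm pt qnorm rnorm runif rbinom sd var median
#'   p.adjust setNames cor complete.cases rpois
#' @importFrom utils head
NULL

stop_format <- function(msg, ...) {
  rlang::abort(message = sprintf(msg, ...), class = "proxiscore_format_error")
}

stop_design <- function(msg, ...) {
  rlang::abort(message = sprintf(msg, ...), class = "proxiscore_design_error")
}

stop_config <- function(msg, ...) {
  rlang::abort(message = sprintf(msg, ...), class = "proxiscore_config_error")
}

stop_contract <- function(msg, ...) {
  rlang::abort(message = sprintf(msg, ...), class = "proxiscore_contract_error")
}

# Derive a reproducible sub-seed for a named pipeline stage from one master
# seed. Keeps every derived seed in the 32-bit integer range.
substream_seed <- function(seed, stage) {
  offsets <- c(
    design = 11L, truth = 29L, intensities = 47L, network = 83L,
    sites = 131L, pipeline = 197L, noise = 271L
  )
  off <- offsets[[stage]] %||% (sum(utf8ToInt(stage)) %% 1000L)
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# Clamp p-values into (0, 1] so that log/product combinations stay finite.
clamp_p <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)
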