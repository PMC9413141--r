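#' @useDynLib lcanet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rgamma
#' @importFrom utils write.csv
NULL

stop_dim <- function(msg) stop(structure(class = c("lcanet_dim_error", "error", "condition"),
                                         list(message = msg, call = sys.call(-1))))

stop_valid <- function(msg) stop(structure(class = c("lcanet_validation_error", "error", "condition"),
                                           list(message = msg, call = sys.call(-1))))

stop_config <- function(msg) stop(structure(class = c("lcanet_config_error", "error", "condition"),
                                            list(message = msg, call = sys.call(-1))))

# coerce 2-D map to (H, W, 1) array
as_map3 <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop_dim("expected a 2-D matrix or 3-D (H, W, C) array")
  x
}

# reflect a 0-based index vector into [0, n-1] (triangular wave), 1-based out
reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- ((i %% p) + p) %% p
  as.integer(ifelse(j < n, j, p - j) + 1L)
}

# sum rows of matrix m into n bins given 1-based bin index per row
scatter_rows <- function(m, idx, n) {
  out <- matrix(0, n, ncol(m))
  s <- rowsum(m, group = idx)
  out[as.integer(rownames(s)), ] <- s
  out
}
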