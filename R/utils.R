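# Internal helpers shared across modules.

# Round half away from zero (9.988 -> 10, 2.5 -> 3, -2.5 -> -3), unlike
# base round() which rounds half to even.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Clamp and quantize a numeric matrix to integer intensity levels.
quantize_intensity <- function(x, bit_depth) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > bit_depth - 1] <- bit_depth - 1
  storage.mode(x) <- "integer"
  x
}

# Validate a grayscale image matrix: rectangular integer-valued matrix,
# rows = flow axis (downstream = increasing row), columns = across flow.
assert_gray_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(name, " must be a numeric matrix")
  invisible(x)
}

assert_binary_mask <- function(x, name = "mask") {
  if (!is.matrix(x))
    stop(name, " must be a matrix")
  v <- unique(as.vector(x))
  if (!all(v %in% c(0, 1)))
    stop(name, " must contain only 0/1 values")
  invisible(x)
}
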