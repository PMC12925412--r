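# Plain-text serialisation of cone-catch stacks and masks. The pipeline's
# native image format is a simple ASCII container (no binary TIFF
# dependency); masks can additionally be written as portable graymaps.

#' Write a cone-catch image as plain text
#'
#' ASCII container: a header line, dimensions and scale, then the three
#' catch channels and the mask, row-major, six significant digits.
#'
#' @param img a [cone_catch_image()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cone_catch <- function(img, path) {
  stopifnot(inherits(img, "cone_catch_image"))
  d <- dim(img$q)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("wingscape_cone_catch 1",
               paste(d[1], d[2], format(img$px_per_cm, digits = 10))), con)
  for (ch in 1:3)
    writeLines(apply(signif(img$q[, , ch], 6), 1, paste, collapse = " "), con)
  writeLines(apply(img$mask + 0L, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read a cone-catch image written by [write_cone_catch()]
#'
#' @param path input file.
#' @return A [cone_catch_image()].
#' @export
read_cone_catch <- function(path) {
  if (!file.exists(path)) stop("no such cone-catch file: ", path)
  lines <- readLines(path)
  if (lines[1] != "wingscape_cone_catch 1")
    stop(path, " is not a wingscape cone-catch file")
  hdr <- as.numeric(strsplit(lines[2], " ")[[1]])
  nr <- hdr[1]; nc <- hdr[2]
  vals <- lapply(strsplit(lines[-(1:2)], " "), as.numeric)
  m <- do.call(rbind, vals)
  if (nrow(m) != 4 * nr || ncol(m) != nc) stop("corrupt cone-catch file: ", path)
  q <- array(0, c(nr, nc, 3))
  for (ch in 1:3) q[, , ch] <- m[((ch - 1) * nr + 1):(ch * nr), ]
  cone_catch_image(q, m[(3 * nr + 1):(4 * nr), ] > 0.5, hdr[3])
}

#' Write a binary mask as a plain PGM (P2) image
#'
#' @param mask logical matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_pgm <- function(mask, path) {
  mask <- as.matrix(mask) > 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mask), nrow(mask)), "255"), con)
  writeLines(apply(mask * 255L, 1, paste, collapse = " "), con)
  invisible(path)
}

# FNV-1a hash of a serialised R object, as 8 hex digits; used to stamp run
# outputs so identical configs are recognisable
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 21661362L   # FNV-style rolling hash confined to 31 bits
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- as.integer((h * 16777619) %% 2147483647)
  }
  sprintf("%08x", h)
}

# CSV with a first comment line embedding config hash and seed
write_run_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# wingscape config=%s seed=%s", hash, seed), con)
  close(con)
  suppressWarnings(write.table(df, path, append = TRUE, sep = ",",
                               row.names = FALSE, qmethod = "double"))
  invisible(path)
}

read_run_csv <- function(path) read.csv(path, comment.char = "#")
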