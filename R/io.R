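# Frame I/O: netpbm PGM (binary P5 and plain-text P2) and raw planar
# YUV420. PGM is used instead of PNG because no PNG codec is available in
# the supported dependency set; any PGM-capable tool (ImageMagick, netpbm,
# Python imageio) converts losslessly.

#' Read / write 8-bit grayscale PGM images
#'
#' Supports binary (`P5`) and plain-text (`P2`) netpbm grayscale with
#' maxval <= 255; comments (`#`) in the header are honoured.
#'
#' @param path file path.
#' @return `read_pgm`: integer matrix (rows x cols, values 0--255).
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  # pull whitespace-separated header tokens, skipping comments
  read_token <- function() {
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) stop("unexpected end of PGM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
      } else if (!grepl("[[:space:]]", ch)) {
        word <- ch
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || grepl("[[:space:]]", ch)) break
          word <- paste0(word, ch)
        }
        return(word)
      }
    }
  }
  magic <- read_token()
  if (!magic %in% c("P5", "P2")) stop("not a PGM file: magic ", magic)
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (is.na(w) || is.na(h) || is.na(maxval) || maxval > 255)
    stop("unsupported PGM header")
  if (magic == "P5") {
    px <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    px <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  if (length(px) != w * h) stop("truncated PGM pixel data")
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}

#' @param img numeric/integer matrix of 8-bit values.
#' @param type `"P5"` (binary) or `"P2"` (plain text).
#' @rdname read_pgm
#' @return `write_pgm`: `path`, invisibly.
#' @export
write_pgm <- function(img, path, type = c("P5", "P2")) {
  type <- match.arg(type)
  if (any(img < 0 | img > 255)) stop("pixel values must lie in [0, 255]")
  img <- round(img)
  h <- nrow(img); w <- ncol(img)
  if (type == "P5") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(as.integer(t(img))), con)
  } else {
    lines <- c(sprintf("P2\n%d %d\n255", w, h),
               apply(img, 1, paste, collapse = " "))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a directory of PGM frames in lexicographic order
#'
#' @param dir directory containing `*.pgm` frames.
#' @return list of integer matrices.
#' @export
read_frames_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.pgm$", full.names = TRUE))
  if (length(files) == 0) stop("no .pgm frames in ", dir)
  lapply(files, read_pgm)
}

#' Read the luma plane of a raw planar YUV420 file
#'
#' @param path raw `.yuv` file (8-bit planar 4:2:0).
#' @param width,height frame dimensions in pixels.
#' @return list of integer luma matrices, one per frame.
#' @export
read_yuv420 <- function(path, width, height) {
  frame_bytes <- width * height * 3 / 2
  sz <- file.size(path)
  nfr <- floor(sz / frame_bytes)
  if (nfr < 1) stop("file smaller than one YUV420 frame")
  con <- file(path, "rb")
  on.exit(close(con))
  lapply(seq_len(nfr), function(i) {
    y <- as.integer(readBin(con, "raw", n = width * height))
    readBin(con, "raw", n = frame_bytes - width * height)  # skip chroma
    matrix(y, nrow = height, ncol = width, byrow = TRUE)
  })
}
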