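# Built-in 5x7 monospaced bitmap font used to burn annotation text into
# phantom images, so rendering never depends on system fonts. Each glyph is
# seven 5-bit rows; unknown characters render as blanks.

font5x7 <- list(
  "A" = c("01110","10001","10001","11111","10001","10001","10001"),
  "B" = c("11110","10001","11110","10001","10001","10001","11110"),
  "C" = c("01110","10001","10000","10000","10000","10001","01110"),
  "D" = c("11110","10001","10001","10001","10001","10001","11110"),
  "E" = c("11111","10000","11110","10000","10000","10000","11111"),
  "F" = c("11111","10000","11110","10000","10000","10000","10000"),
  "G" = c("01110","10001","10000","10111","10001","10001","01111"),
  "H" = c("10001","10001","11111","10001","10001","10001","10001"),
  "I" = c("01110","00100","00100","00100","00100","00100","01110"),
  "J" = c("00111","00010","00010","00010","10010","10010","01100"),
  "K" = c("10001","10010","11100","10010","10001","10001","10001"),
  "L" = c("10000","10000","10000","10000","10000","10000","11111"),
  "M" = c("10001","11011","10101","10101","10001","10001","10001"),
  "N" = c("10001","11001","10101","10011","10001","10001","10001"),
  "O" = c("01110","10001","10001","10001","10001","10001","01110"),
  "P" = c("11110","10001","11110","10000","10000","10000","10000"),
  "Q" = c("01110","10001","10001","10001","10101","10010","01101"),
  "R" = c("11110","10001","11110","10100","10010","10001","10001"),
  "S" = c("01111","10000","01110","00001","00001","10001","01110"),
  "T" = c("11111","00100","00100","00100","00100","00100","00100"),
  "U" = c("10001","10001","10001","10001","10001","10001","01110"),
  "V" = c("10001","10001","10001","10001","10001","01010","00100"),
  "W" = c("10001","10001","10001","10101","10101","11011","10001"),
  "X" = c("10001","10001","01010","00100","01010","10001","10001"),
  "Y" = c("10001","01010","00100","00100","00100","00100","00100"),
  "Z" = c("11111","00001","00010","00100","01000","10000","11111"),
  "0" = c("01110","10001","10011","10101","11001","10001","01110"),
  "1" = c("00100","01100","00100","00100","00100","00100","01110"),
  "2" = c("01110","10001","00001","00110","01000","10000","11111"),
  "3" = c("11111","00010","00100","00010","00001","10001","01110"),
  "4" = c("00010","00110","01010","10010","11111","00010","00010"),
  "5" = c("11111","10000","11110","00001","00001","10001","01110"),
  "6" = c("00110","01000","10000","11110","10001","10001","01110"),
  "7" = c("11111","00001","00010","00100","01000","01000","01000"),
  "8" = c("01110","10001","10001","01110","10001","10001","01110"),
  "9" = c("01110","10001","10001","01111","00001","00010","01100"),
  ":" = c("00000","01100","01100","00000","01100","01100","00000"),
  "." = c("00000","00000","00000","00000","00000","01100","01100"),
  "'" = c("00100","00100","01000","00000","00000","00000","00000"),
  "-" = c("00000","00000","00000","11111","00000","00000","00000"),
  "/" = c("00001","00010","00100","00100","00100","01000","10000"),
  " " = c("00000","00000","00000","00000","00000","00000","00000")
)

glyph_matrix <- function(ch) {
  g <- font5x7[[ch]]
  if (is.null(g)) g <- font5x7[[" "]]
  matrix(as.integer(unlist(strsplit(g, ""))), nrow = 7, ncol = 5, byrow = TRUE)
}

# Burn `text` into matrix `px` (grayscale) with top-left anchor (row0, col0),
# 1-based, integer scale factor, intensity `value`. Returns the modified
# matrix; clipping at the canvas edge is silent.
draw_text <- function(px, text, row0, col0, scale = 2, value = 255) {
  h <- nrow(px); w <- ncol(px)
  chars <- strsplit(toupper(text), "")[[1]]
  col <- col0
  for (ch in chars) {
    g <- glyph_matrix(ch)
    big <- g[rep(seq_len(7), each = scale), rep(seq_len(5), each = scale)]
    rr <- row0:(row0 + nrow(big) - 1L)
    cc <- col:(col + ncol(big) - 1L)
    ok_r <- rr >= 1 & rr <= h; ok_c <- cc >= 1 & cc <= w
    if (any(ok_r) && any(ok_c)) {
      sub <- big[ok_r, ok_c, drop = FALSE]
      block <- px[rr[ok_r], cc[ok_c], drop = FALSE]
      block[sub > 0] <- value
      px[rr[ok_r], cc[ok_c]] <- block
    }
    col <- col + 6L * scale   # 5-px glyph + 1-px gap
  }
  px
}

text_width_px <- function(text, scale = 2) 6L * scale * nchar(text)
text_height_px <- function(scale = 2) 7L * scale
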