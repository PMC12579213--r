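# Shared fixture builders; everything is generated in code at test time.

deg2rad_test <- function(x) x * pi / 180

disk_mask <- function(radius, shape = c(2 * radius + 21, 2 * radius + 21),
                      center = (shape + 1) / 2) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((rr - center[1])^2 + (cc - center[2])^2 <= radius^2) * 1
}

rect_mask <- function(h, w, shape = c(h + 20, w + 20)) {
  m <- matrix(0, shape[1], shape[2])
  r0 <- floor((shape[1] - h) / 2) + 1
  c0 <- floor((shape[2] - w) / 2) + 1
  m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- 1
  m
}

dilate_disk <- function(mask, radius) {
  EBImage::imageData(EBImage::dilate(EBImage::Image(mask),
                                     EBImage::makeBrush(2 * radius + 1, "disc")))
}

erode_disk <- function(mask, radius) {
  EBImage::imageData(EBImage::erode(EBImage::Image(mask),
                                    EBImage::makeBrush(2 * radius + 1, "disc")))
}
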