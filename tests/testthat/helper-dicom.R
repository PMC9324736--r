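# Test-only writer of minimal part-10 DICOM files (explicit VR, little
# endian, one uint16 monochrome frame per file) so the series reader can be
# exercised without binary fixtures in the repository.

write_test_dicom <- function(path, img, position = c(0, 0, 0), instance = 1L,
                             pixel_spacing = c(1, 1), slice_thickness = 1,
                             orientation = c(1, 0, 0, 0, 1, 0)) {
  u16le <- function(x) {
    x <- as.integer(x)
    as.raw(c(x %% 256L, x %/% 256L))
  }
  u32le <- function(x) {
    as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
  }
  pad_even <- function(b, pad = as.raw(0x20)) if (length(b) %% 2L) c(b, pad) else b

  elem <- function(group, element, vr, body) {
    head <- c(u16le(group), u16le(element), charToRaw(vr))
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      c(head, raw(2), u32le(length(body)), body)
    } else {
      c(head, u16le(length(body)), body)
    }
  }
  str_el <- function(group, element, vr, s, pad = as.raw(0x20)) {
    elem(group, element, vr, pad_even(charToRaw(s), pad))
  }
  ds <- function(x) paste(format(x, trim = TRUE, scientific = FALSE), collapse = "\\")

  meta <- c(
    str_el(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.4", as.raw(0)),
    str_el(0x0002, 0x0003, "UI", "1.2.3.4.5.6.7.1", as.raw(0)),
    str_el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1", as.raw(0))
  )

  pix <- as.integer(round(t(img)))  # row-major pixel order
  stopifnot(all(pix >= 0), all(pix < 32768))
  pix_body <- writeBin(pix, raw(), size = 2L, endian = "little")

  body <- c(
    str_el(0x0008, 0x0060, "CS", "MR"),
    str_el(0x0018, 0x0050, "DS", ds(slice_thickness)),
    str_el(0x0020, 0x000e, "UI", "1.2.3.4.5.6.7.8.9", as.raw(0)),
    str_el(0x0020, 0x0013, "IS", ds(instance)),
    str_el(0x0020, 0x0032, "DS", ds(position)),
    str_el(0x0020, 0x0037, "DS", ds(orientation)),
    elem(0x0028, 0x0010, "US", u16le(nrow(img))),
    elem(0x0028, 0x0011, "US", u16le(ncol(img))),
    str_el(0x0028, 0x0030, "DS", ds(pixel_spacing)),
    elem(0x0028, 0x0100, "US", u16le(16L)),
    elem(0x0028, 0x0103, "US", u16le(0L)),
    elem(0x7fe0, 0x0010, "OW", pix_body)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# write a whole series; slice i of vol (slice, row, col) becomes one file,
# with deliberately shuffled file names to prove position-based sorting
write_test_dicom_series <- function(dir, vol, shuffle_names = TRUE,
                                    slice_thickness = 3.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(vol)[1]
  order_names <- if (shuffle_names) rev(seq_len(nz)) else seq_len(nz)
  for (i in seq_len(nz)) {
    write_test_dicom(
      file.path(dir, sprintf("img_%03d.dcm", order_names[i])),
      vol[i, , ],
      position = c(0, 0, (i - 1) * slice_thickness),
      instance = i, slice_thickness = slice_thickness
    )
  }
  invisible(dir)
}
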