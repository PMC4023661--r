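# Shared generators and independent oracles for property-style tests.

# random labeled matrix; optionally with MISSING cells and awkward labels
random_heat_matrix <- function(R = sample(1:12, 1), C = sample(1:12, 1),
                               p_missing = 0.15, awkward_labels = FALSE) {
  vals <- matrix(round(stats::runif(R * C, -100, 100), 4), R, C)
  flags <- matrix(ifelse(stats::runif(R * C) < p_missing, "MISSING", "NONE"),
                  R, C)
  vals[flags == "MISSING"] <- NA_real_
  mk_label <- function(prefix, k) {
    if (awkward_labels && stats::runif(1) < 0.4)
      sample(c(sprintf("%s %d, extra", prefix, k),
               sprintf('say "%s%d"', prefix, k),
               sprintf("%s,%d", prefix, k)), 1)
    else sprintf("%s%d", prefix, k)
  }
  heat_matrix(vals,
              vapply(seq_len(R), function(i) mk_label("row", i), character(1)),
              vapply(seq_len(C), function(j) mk_label("col", j), character(1)),
              flags)
}

# Independent interpolation oracle: clamps, picks the half around the
# midpoint, and delegates the per-channel linear blend to grDevices::colorRamp
# (a code path the implementation never touches), then applies the same
# round-half-up / hex conventions.
oracle_color <- function(v, scheme, rmin, rmid, rmax) {
  v <- min(max(v, rmin), rmax)
  stops <- scheme$stops
  if (v <= rmid && rmid > rmin) {
    ramp <- grDevices::colorRamp(c(stops$color[1], stops$color[2]),
                                 space = "rgb", interpolate = "linear")
    ch <- ramp((v - rmin) / (rmid - rmin))
  } else {
    ramp <- grDevices::colorRamp(c(stops$color[2], stops$color[3]),
                                 space = "rgb", interpolate = "linear")
    t <- if (rmax > rmid) (v - rmid) / (rmax - rmid) else 0
    ch <- ramp(t)
  }
  ch <- floor(ch + 0.5)
  sprintf("#%02x%02x%02x", ch[1], ch[2], ch[3])
}

svg_xml <- function(doc) xml2::read_xml(svg_string(doc))

count_id_prefix <- function(xml, prefix) {
  length(xml2::xml_find_all(
    xml, sprintf('//*[starts-with(@id, "%s")]', prefix)))
}

fill_of_id <- function(xml, id) {
  node <- xml2::xml_find_first(xml, sprintf('//*[@id = "%s"]', id))
  xml2::xml_attr(node, "fill")
}
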