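# Builds the packaged annotation fixtures:
#   inst/extdata/cytoBand.hg19.synthetic.txt  (UCSC cytoBand.txt dialect)
#   inst/extdata/genes.hg19.synthetic.bed     (BED6)
#
# The files are SYNTHETIC approximations of hg19: bands that the analysis or
# the simulator names ("anchor" bands) sit at approximately real hg19
# coordinates; the remainder of each arm is tiled with filler bands (labelled
# pf*/qf*) so that every base belongs to exactly one band and one arm.
# Gene coordinates are approximate and guaranteed to lie inside their stated
# band. Only band/arm membership is treated as ground truth downstream.
#
# Rerun from the repo root:  Rscript data-raw/make_annotation.R

chrom_len <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566)

# acen intervals [cen_start, cen_mid) = p11.1, [cen_mid, cen_end) = q11.1
cen <- list(
  "1" = c(121500000, 125000000, 128900000),
  "2" = c(91000000, 93300000, 95300000),
  "3" = c(89500000, 91000000, 93500000),
  "4" = c(48200000, 50400000, 52700000),
  "5" = c(46100000, 48400000, 50700000),
  "6" = c(58700000, 61000000, 63300000),
  "7" = c(58000000, 59900000, 61700000),
  "8" = c(43100000, 45600000, 48100000),
  "9" = c(47300000, 49000000, 50700000),
  "10" = c(38000000, 40200000, 42300000),
  "11" = c(51600000, 53700000, 55700000),
  "12" = c(33300000, 35800000, 38200000),
  "13" = c(16300000, 17900000, 19500000),
  "14" = c(16100000, 17600000, 19100000),
  "15" = c(15800000, 19000000, 20700000),
  "16" = c(35300000, 36600000, 38300000),
  "17" = c(22200000, 24000000, 25800000),
  "18" = c(15400000, 17200000, 19000000),
  "19" = c(24400000, 26500000, 28600000),
  "20" = c(25600000, 27500000, 29400000),
  "21" = c(10900000, 13200000, 14300000),
  "22" = c(12200000, 14700000, 17900000),
  "X" = c(58100000, 60600000, 63000000),
  "Y" = c(11600000, 12500000, 13400000))

# anchor bands: chrom, name, start, end (0-based half-open, approx real hg19)
anchors <- rbind(
  data.frame(chrom = "1", name = c("p36.21", "p21", "p13", "p12", "q32.1"),
             start = c(12700000, 94300000, 107200000, 116100000, 198700000),
             end   = c(16200000, 106700000, 116100000, 120600000, 205300000)),
  data.frame(chrom = "4", name = c("q12", "q13.3"),
             start = c(52700000, 68600000),
             end   = c(59500000, 75300000)),
  data.frame(chrom = "5", name = "q34", start = 160500000, end = 168900000),
  data.frame(chrom = "6", name = "q25", start = 149000000, end = 161000000),
  data.frame(chrom = "7",
             name = c("p22.1", "p21.3", "p21.2", "p21.1", "p12.3", "p12.2",
                      "p12.1", "p11.2", "q21.2", "q21.3", "q22.3", "q31.2"),
             start = c(4500000, 7300000, 13800000, 16500000, 45400000,
                       49000000, 50500000, 53900000, 91100000, 92800000,
                       104500000, 114600000),
             end   = c(7300000, 13800000, 16500000, 20900000, 49000000,
                       50500000, 53900000, 58000000, 92800000, 98000000,
                       107400000, 117400000)),
  data.frame(chrom = "11",
             name = c("p15.3", "p13", "p11.2", "q13.3", "q25"),
             start = c(10700000, 31000000, 43500000, 68700000, 130300000),
             end   = c(12700000, 36400000, 48800000, 70500000, 135006516)),
  data.frame(chrom = "12",
             name = c("q13.12", "q13.13", "q13.2", "q13.3", "q14.1", "q14.2",
                      "q14.3", "q15", "q21.1"),
             start = c(49200000, 51700000, 54400000, 56200000, 58100000,
                       62700000, 64400000, 67500000, 71500000),
             end   = c(51700000, 54400000, 56200000, 58100000, 62700000,
                       64400000, 67500000, 71500000, 75700000)),
  data.frame(chrom = "16", name = c("q12.1", "q12.2"),
             start = c(46400000, 52600000), end = c(52600000, 56700000)),
  data.frame(chrom = "17",
             name = c("p13.1", "q11.2", "q12", "q21", "q22", "q23", "q24",
                      "q25.1"),
             start = c(6500000, 25800000, 31800000, 38100000, 50200000,
                       57600000, 62600000, 70900000),
             end   = c(10700000, 31800000, 38100000, 50200000, 57600000,
                       62600000, 67400000, 74800000)))

fill_arm <- function(chrom, arm, lo, hi, occupied, n_fill = 3L) {
  # tile [lo,hi) minus occupied anchor intervals with filler bands pf1,pf2,...
  occ <- occupied[order(occupied$start), , drop = FALSE]
  gaps <- list(); cur <- lo
  for (i in seq_len(nrow(occ))) {
    if (occ$start[i] > cur) gaps[[length(gaps) + 1]] <- c(cur, occ$start[i])
    cur <- max(cur, occ$end[i])
  }
  if (cur < hi) gaps[[length(gaps) + 1]] <- c(cur, hi)
  out <- list(); k <- 0L
  for (g in gaps) {
    # split long gaps so filler bands stay < ~40 Mb
    nsub <- max(1L, ceiling((g[2] - g[1]) / 4e7))
    cuts <- round(seq(g[1], g[2], length.out = nsub + 1))
    for (j in seq_len(nsub)) {
      k <- k + 1L
      out[[k]] <- data.frame(chrom = chrom,
                             name = sprintf("%sf%d", arm, k),
                             start = cuts[j], end = cuts[j + 1])
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

bands <- list()
for (ch in names(chrom_len)) {
  cc <- cen[[ch]]
  anc <- anchors[anchors$chrom == ch, , drop = FALSE]
  anc_p <- anc[startsWith(anc$name, "p"), , drop = FALSE]
  anc_q <- anc[startsWith(anc$name, "q"), , drop = FALSE]
  p <- rbind(anc_p[, c("chrom", "name", "start", "end")],
             fill_arm(ch, "p", 0, cc[1], anc_p[, c("start", "end")]))
  q <- rbind(anc_q[, c("chrom", "name", "start", "end")],
             fill_arm(ch, "q", cc[3], chrom_len[[ch]],
                      anc_q[, c("start", "end")]))
  acen <- data.frame(chrom = ch, name = c("p11.1", "q11.1"),
                     start = c(cc[1], cc[2]), end = c(cc[2], cc[3]))
  b <- rbind(p, acen, q)
  b <- b[order(b$start), ]
  stopifnot(b$start[1] == 0, b$end[nrow(b)] == chrom_len[[ch]],
            all(b$start[-1] == b$end[-nrow(b)]))
  b$stain <- ifelse(b$name %in% c("p11.1", "q11.1"), "acen",
                    rep_len(c("gneg", "gpos50"), nrow(b)))
  bands[[ch]] <- b
}
bands <- do.call(rbind, bands)
bands$chrom <- paste0("chr", bands$chrom)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.table(bands[, c("chrom", "start", "end", "name", "stain")],
            "inst/extdata/cytoBand.hg19.synthetic.txt",
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

# ---- gene catalog (approximate hg19 loci, inside their stated bands) ----
g <- function(chrom, start, end, sym) data.frame(chrom, start, end, sym)
genes <- rbind(
  # 7p11.2  [53.9, 58.0 Mb)
  g("7", 54609000, 54663000, "VSTM2A"),
  g("7", 54820000, 54826000, "SEC61G"),
  g("7", 55086714, 55324313, "EGFR"),
  g("7", 55433000, 55506000, "LANCL2"),
  g("7", 55540000, 55680000, "VOPP1"),
  # 12q13.3 [56.2, 58.1 Mb)
  g("12", 57420000, 57440000, "ARHGEF25"),
  g("12", 57610000, 57620000, "PIP4K2C"),
  g("12", 57870000, 57900000, "MARS"),
  g("12", 57920000, 57936000, "DCTN2"),
  g("12", 57940000, 57976000, "KIF5A"),
  g("12", 57998000, 58006000, "DTX3"),
  g("12", 58009000, 58014000, "SLC26A10"),
  g("12", 58020000, 58030000, "B4GALNT1"),
  # 12q14.1 [58.1, 62.7 Mb)
  g("12", 58118000, 58135000, "AGAP2"),
  g("12", 58142000, 58146000, "CDK4"),
  g("12", 58156000, 58161000, "CYP27B1"),
  g("12", 58162000, 58166000, "METTL1"),
  g("12", 58168000, 58174000, "METT21B"),
  g("12", 58176000, 58189000, "TSFM"),
  g("12", 58191000, 58211000, "AVIL"),
  g("12", 58213000, 58240000, "CTDSP2"),
  g("12", 58250000, 58277000, "OS9"),
  # 12q15  [67.5, 71.5 Mb)
  g("12", 69201000, 69239000, "MDM2"),
  g("12", 69244000, 69328000, "CPM"),
  g("12", 69660000, 69688000, "ATP23"),
  # 4q12   [52.7, 59.5 Mb)
  g("4", 53001000, 53481000, "SCFD2"),
  g("4", 54240000, 54320000, "FIP1L1"),
  g("4", 55095264, 55164414, "PDGFRA"),
  g("4", 55524085, 55606881, "KIT"),
  # 1q32.1 [198.7, 205.3 Mb)
  g("1", 204042000, 204096000, "SOX13"),
  g("1", 204100000, 204135000, "ETNK2"),
  g("1", 204150000, 204163000, "REN"),
  g("1", 204190000, 204196000, "KISS1"),
  g("1", 204200000, 204230000, "GOLT1A"),
  g("1", 204240000, 204300000, "PLEKHA6"),
  g("1", 204400000, 204470000, "PIK3C2B"),
  g("1", 204485000, 204527000, "MDM4"),
  g("1", 204582000, 204654000, "LRRN2"))

bed <- data.frame(chrom = paste0("chr", genes$chrom),
                  start = genes$start, end = genes$end,
                  name = genes$sym, score = 0L, strand = "+")
write.table(bed, "inst/extdata/genes.hg19.synthetic.bed",
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

cat("wrote", nrow(bands), "bands,", nrow(bed), "genes\n")
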