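# printed evaluation counts for a published 73-SNP panel run on 1800
# simulated genotypes (13 simulated categories x 7 assigned categories),
# used as the worked-example input for the metric definitions
panel_eval_confusion <- function() {
  cats <- c("DLB", "FLB", "NLB", "DLB-FLB", "DLB-NLB", "NLB-FLB",
            "Triple Hybrid")
  rows <- c("DLB", "FLB", "NLB",
            "DLB-FLB F1", "DLB-FLB F2:F4", "DLB-FLB BX",
            "DLB-NLB F1", "DLB-NLB F2:F4", "DLB-NLB BX",
            "NLB-FLB F1", "NLB-FLB F2:F4", "NLB-FLB BX",
            "Triple Hybrid")
  m <- matrix(0L, 13, 7, dimnames = list(rows, cats))
  m["DLB", "DLB"] <- 100L
  m["FLB", "FLB"] <- 100L
  m["NLB", "NLB"] <- 100L
  m["DLB-FLB F1", "DLB-FLB"] <- 50L
  m["DLB-FLB F2:F4", c("DLB-FLB", "Triple Hybrid")] <- c(149L, 1L)
  m["DLB-FLB BX", c("DLB", "DLB-FLB")] <- c(2L, 198L)
  m["DLB-NLB F1", "DLB-NLB"] <- 50L
  m["DLB-NLB F2:F4", "DLB-NLB"] <- 150L
  m["DLB-NLB BX", c("NLB", "DLB-NLB")] <- c(1L, 199L)
  m["NLB-FLB F1", c("NLB-FLB", "Triple Hybrid")] <- c(47L, 3L)
  m["NLB-FLB F2:F4", c("NLB-FLB", "Triple Hybrid")] <- c(131L, 19L)
  m["NLB-FLB BX", c("DLB-FLB", "DLB-NLB", "NLB-FLB", "Triple Hybrid")] <-
    c(1L, 2L, 193L, 4L)
  m["Triple Hybrid", c("DLB-FLB", "Triple Hybrid")] <- c(4L, 296L)
  m
}

# the percent metrics printed alongside those counts, to two decimals
panel_eval_metrics <- function() {
  data.frame(
    category = c("DLB", "FLB", "NLB", "DLB-FLB", "DLB-NLB", "NLB-FLB",
                 "Triple Hybrid"),
    efficiency = c(100.00, 100.00, 100.00, 99.25, 99.75, 92.75, 98.67),
    accuracy = c(98.04, 100.00, 99.01, 98.76, 99.50, 100.00, 91.64),
    performance = c(98.04, 100.00, 99.01, 98.02, 99.25, 92.75, 90.42),
    stringsAsFactors = FALSE
  )
}
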