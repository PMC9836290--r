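# Golden fixture: spreadsheet-style derivation

One gene (`geneA`, chr1:101-700, `+`, length 600) and six samples:
controls C1/C2/C3 harvested at 1/2/3 h of recovery, treated T2/T3/T4 at
2/3/4 h, one replicate. Six genomic positions carry reads (see
`counts.tsv`); position 110 lies in the gene but outside its internal
window, 900 is intergenic, 200 is a low-coverage position.

## Stage 1 — low-coverage filter (< 3 reads discarded, per sample)

Position 200 (counts 2,1,0,2,1,0) is discarded in every sample and drops
out of the analysis. T4's count at 660 (= 2) is discarded for T4 only;
all other cells are >= 3 and retained (the boundary value 3 would be
retained). Union of retained positions: 110, 140, 300, 660, 900.

## Stage 2 — quantile normalization (union matrix, zeros filled)

Matrix (rows = positions, T4@660 contributes 0):

|     |  C1|  C2|  C3|  T2|  T3|  T4|
|-----|----|----|----|----|----|----|
| 110 |  10|  10|  10|  10|  10|  10|
| 140 |  20|  24|  30|   8|   6|   4|
| 300 |  40|  44|  50|  12|  10|   6|
| 660 |  30|  36|  40|  10|   8|   0|
| 900 |  60|  60|  60|  70|  80|  90|

Sorted columns and across-sample rank means:

rank 1: (10+10+10+8+6+0)/6  = 44/6 = 22/3
rank 2: (20+24+30+10+8+4)/6 = 96/6 = 16
rank 3: (30+36+40+10+10+6)/6 = 132/6 = 22
rank 4: (40+44+50+12+10+10)/6 = 166/6 = 83/3
rank 5: (60+60+60+70+80+90)/6 = 420/6 = 70
(column total after normalization: 143)

Reassignment by rank; ties get the mean of the spanned rank means:
T2 has 10 twice (ranks 2-3): (16+22)/2 = 19; T3 has 10 twice (ranks
3-4): (22+83/3)/2 = 149/6. T4's masked cell at 660 stays 0 (it is not a
retained site of T4), so T4's retained total is 143 - 22/3 = 407/3.

## Stage 3 — gene aggregation over the internal window

Window: win_start = 101 + floor(0.05*600) = 131, win_end = 700 - 30 =
670; in-window positions: 140, 300, 660 (110 and 900 excluded, but both
count in each sample's genome-wide total).

| sample | reads (window sum) | sites | total | frequency |
|--------|--------------------|-------|-------|-----------|
| C1     | 16+83/3+22 = 197/3 | 3     | 143   | 197/429   |
| C2     | 197/3              | 3     | 143   | 197/429   |
| C3     | 197/3              | 3     | 143   | 197/429   |
| T2     | 22/3+83/3+19 = 54  | 3     | 143   | 54/143    |
| T3     | 22/3+149/6+16 = 289/6 | 3  | 143   | 289/858   |
| T4     | 16+22 = 38         | 2     | 407/3 | 114/407   |

## Stage 4 — generation-matched pairs and log2 fold changes

Pairs (offset 1 h): (T2,C1), (T3,C2), (T4,C3).

FC(2h) = log2((54/143)/(197/429))   = log2(162/197)    = -0.2822018166
FC(3h) = log2((289/858)/(197/429))  = log2(289/394)    = -0.4471261370
FC(4h) = log2((114/407)/(197/429))  = log2(48906/80179) = -0.7132129521

## Stage 5 — classification

Defaults: length 600 > 200 ok; control sites at the final pair (C3) = 3,
not > 5 -> fails; |FC(4h)| = 0.713, not > 1 -> fails; signs consistent
and |FC| grows monotonically -> amplified ok. Verdict: excluded.

With min_control_sites = 2 and fc_threshold = 0.5 all four criteria
hold and the final FC is negative: verdict depleted_hit.
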