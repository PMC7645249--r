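# Synthetic example of a cost-adjustment table (not real exchange or
# inflation data). Currency rates are year-average EUR per unit of the
# local currency for the publication year; inflation factors bring costs
# from the publication year to 2017 for the given country.
currencies:
  GBP:
    2015: 1.378
    2016: 1.224
  SEK:
    2014: 0.110
  PLN:
    2016: 0.229
inflation:
  SYN01:
    2015: 1.031
    2016: 1.018
  SYN02:
    2014: 1.052
  SYN03:
    2016: 1.024
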