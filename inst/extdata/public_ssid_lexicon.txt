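# Public-network name lexicon: one pattern per line, matched
# case-insensitively as a SUBSTRING of the SSID. Networks whose name
# contains "guest" are classified public by a separate built-in rule and
# never reach this list. Edit freely: the list stands in for a manual
# classification of hotel / library / transit / cafe chains.
free
public
library
airport
transit
cta
metra
amtrak
hotel
cafe
café
mcdonald
starbucks
dunkin
university
college
xfinitywifi
attwifi
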