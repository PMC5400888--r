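# term	pos	neg - simplified 3-column sentiment fixture (synthetic scores)
good	0.7	0
great	0.8	0
happy	0.75	0
glad	0.7	0
hopeful	0.7	0
wonderful	0.8	0
thankful	0.75	0
grateful	0.8	0
blessed	0.7	0
relieved	0.7	0
encouraging	0.6	0
lucky	0.6	0
hope	0.6	0
love	0.7	0
positive	0.6	0
better	0.5	0
comfort	0.5	0
worried	0	0.7
scared	0	0.8
afraid	0	0.75
anxious	0	0.7
sad	0	0.7
depressed	0	0.8
terrible	0	0.8
awful	0	0.8
hopeless	0	0.85
devastated	0	0.9
stressed	0	0.7
frustrated	0	0.7
upset	0	0.7
nervous	0	0.6
miserable	0	0.8
lonely	0	0.6
fear	0	0.7
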