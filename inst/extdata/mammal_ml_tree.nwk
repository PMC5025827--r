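((((((((1:0.0759,(2:0.0568,3:0.0467)47:0.0234)48:0.00318,(((4:0.0448,5:0.0626)49:0.00468,((6:0.0656,7:0.0707)50:0.00570,(8:0.0634,9:0.0616)51:0.00210)52:0.0142)53:0.0150,((10:0.0602,(((11:0.0383,(12:0.0233,13:0.0128)54:0.0165)55:0.00491,14:0.0721)56:0.00919,15:0.0666)57:0.00518)58:0.0222,16:0.0559)59:0.00143)60:0.000543)61:0.00249,(17:0.1007,(18:0.0849,(19:0.1390,20:0.1468)62:0.0152)63:0.00163)64:0.00940)65:0.0110,(((21:0.0989,22:0.0676)66:0.0303,(23:0.1102,((24:0.0777,25:0.1875)67:0.00944,(26:0.0941,27:0.1660)68:0.00225)69:0.0131)70:0.00528)71:0.00149,((28:0.0618,(29:0.0913,(30:0.0414,31:0.0231)72:0.0368)73:0.00438)74:0.00775,(32:0.00806,33:0.00966)75:0.0581)76:0.00177)77:0.00997)78:0.0107,(34:0.0664,35:0.0869)79:0.0309)80:0.00230,((36:0.0429,(37:0.1000,38:0.0439)81:0.00304)82:0.0133,(39:0.0695,((40:0.1506,41:0.0760)83:0.00679,42:0.1275)84:0.00331)85:0.00283)86:0.0300)87:0.1278,(43:0.0834,44:0.0739)88:0.1754)89:0.1518,(45:0.0454,46:0.0378)90:0.1518)91:0.0000;
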