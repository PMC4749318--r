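station,year,net_hours,net_hours_window
BICA,2008,572.3,572.3
LATA,2008,520.5,520.5
SATA,2008,414.7,414.7
KIFI,2008,406.7,406.7
MTAP,2008,421.7,421.7
OBYA,2008,561.2,561.2
BICA,2009,574.2,574.2
LATA,2009,522.2,522.2
SATA,2009,429.0,429.0
KIFI,2009,450.0,450.0
MTAP,2009,454.0,454.0
OBYA,2009,543.5,543.5
BICA,2010,1407.7,583.7
LATA,2010,1379.8,584.0
SATA,2010,1102.8,463.5
KIFI,2010,1033.3,462.7
MTAP,2010,1078.3,462.7
OBYA,2010,1314.8,539.0
BICA,2011,1590.0,567.3
LATA,2011,1579.0,534.7
SATA,2011,1351.0,470.7
KIFI,2011,1293.8,450.5
MTAP,2011,1295.3,468.7
OBYA,2011,1594.3,574.3
BICA,2012,1066.7,535.0
LATA,2012,1116.7,537.3
SATA,2012,957.3,477.3
KIFI,2012,893.3,449.3
MTAP,2012,847.3,456.8
OBYA,2012,1077.5,518.5
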